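gene_id	ko_id
g0001	K00001
g0002	K00002
g0003	K00001
g0004	K00003
g0005	K00004
g0006	K00002
g0007	K00005
g0008	K00006
g0009	K00006
g0010	K00007
g0011	K00008
g0012	K00003
g0013	K00009
g0014	K00010
g0015	K00011
g0016	K00001
g0017	K00012
g0018	K00012
g0019	K00005
g0020	K00008
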