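ko_id	reaction_id
K00001	R00001
K00002	R00002
K00003	R00003
K00004	R00004
K00005	R00005
K00006	R00006
K00007	R00007
K00008	R00008
K00009	R00009
K00010	R00010
K00099	R09999
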