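ENTRY       R00001  Reaction
EQUATION    C00031 => C00022
///
ENTRY       R00002  Reaction
EQUATION    C00022 + C00003 <=> C00024 + C00004
///
ENTRY       R00003  Reaction
EQUATION    2 C00031 => C00118 + C00111
///
ENTRY       R00004  Reaction
EQUATION    C00111 -> C00022
///
ENTRY       R00005  Reaction
EQUATION    C00024 + C00009 <=> C00010 + C00033
///
ENTRY       R00006  Reaction
EQUATION    C00033 => C00084
///
ENTRY       R00007  Reaction
EQUATION    C00084 + C00003 <=> C00033 + C00004
///
ENTRY       R00008  Reaction
EQUATION    (n) C00718 => C00369
///
ENTRY       R00009  Reaction
EQUATION    C00267[c] => C00221[e]
///
ENTRY       R00010  Reaction
EQUATION    C00668 + C00002 => C05345 +
            C00008
///
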