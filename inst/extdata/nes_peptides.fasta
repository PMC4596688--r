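>hRio2/389-403
RSFEMTEFNQALEEI
>CPEB4/379-393
RTFDMHSLESSLIDI
>hRio2-R
IEELAQNFETMEF
>CPEB4-R
IDILSSELSHMDF
>PKI
SNELALKLAGLDI
>PKI-Flip1
IDLNELALKLAGL
>PKI-Flip2
FDLNELALKLAGL
>PKI-Flip3
FDMNELALKLAGL
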