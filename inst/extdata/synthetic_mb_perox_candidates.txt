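Mb_perox001
Mb_perox002
Mb_perox003
Mb_perox004
Mb_perox005
Mb_perox006
Mb_perox007
Mb_perox008
Mb_perox009
Mb_perox010
Mb_perox011
Mb_perox012
Mb_perox013
Mb_perox014
Mb_perox015
Mb_perox016
Mb_perox017
Mb_perox018
Mb_perox019
Mb_perox020
Mb_perox021
Mb_perox022
Mb_perox023
Mb_perox024
Mb_perox025
Mb_perox026
Mb_perox027
Mb_perox028
Mb_perox029
Mb_perox030
Mb_PPP
Mb_Nudt
Mb_myoIDH
Mb_DLDH
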