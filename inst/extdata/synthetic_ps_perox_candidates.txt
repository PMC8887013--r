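Ps_perox001
Ps_perox002
Ps_perox003
Ps_perox004
Ps_perox005
Ps_perox006
Ps_perox007
Ps_perox008
Ps_perox009
Ps_perox010
Ps_perox011
Ps_perox012
Ps_perox013
Ps_perox014
Ps_perox015
Ps_perox016
Ps_perox017
Ps_perox018
Ps_perox019
Ps_perox020
Ps_perox021
Ps_perox022
Ps_perox023
Ps_perox024
Ps_perox025
Ps_perox026
Ps_perox027
Ps_perox028
Ps_perox029
Ps_perox030
Ps_perox031
Ps_perox032
Ps_perox033
Ps_perox034
Ps_perox035
Ps_perox036
Ps_perox037
Ps_perox038
Ps_perox039
Ps_perox040
Ps_perox041
Ps_perox042
Ps_perox043
Ps_perox044
Ps_perox045
Ps_perox046
Ps_perox047
Ps_perox048
Ps_perox049
Ps_perox050
Ps_perox051
Ps_perox052
Ps_perox053
Ps_perox054
Ps_perox055
Ps_perox056
Ps_perox057
Ps_perox058
Ps_perox059
Ps_perox060
Ps_perox061
Ps_perox062
Ps_perox063
Ps_PPP
Ps_Nudt
Ps_myoIDH
Ps_DLDH
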