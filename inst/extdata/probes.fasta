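>S1 glutamate-binding region, first lobe (57 aa)
NSEYVRQNSISAGITAVAEGELDILIGPISVTPERAAIEGITFTQPYFSSGIGLLIP
>S2 glutamate-binding region, second lobe (69 aa)
EAVMFDRPALIYYTRQNPNLNLEVTEIRVSLEPYGFVLKENSPLQKTINVEMLNLLYSRVIAEFTERWL
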