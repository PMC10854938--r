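species,total
Dascyllus reticulatus,115
Neoniphon sammara,106
Abudefduf vaigiensis,105
Canthigaster valentini,110
Pomacentrus moluccensis,118
Zebrasoma scopas,107
Hemigymnus melapterus,104
Lutjanus fulvus,103
Scolopsis bilineata,108
Scaridae,114
Pempheris vanicolensis,102
Plectroglyphidodon dickii,107
Zanclus cornutus,119
Neoglyphidodon nigroris,105
Balistapus undulatus,111
Siganus fuscescens,114
Chromis chrysura,116
Amphiprion clarkii,106
Chaetodon lunulatus,115
Chaetodon trifascialis,119
Myripristis kuntee,112
Acanthurus nigrofuscus,109
Hemigymnus fasciatus,102
Abactochromis labrosus,111
Abalistes stellaris,116
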