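family	species
Rajidae	Amblyraja georgiana (Norman, 1938)
Rajidae	Bathyraja eatonii (Günther, 1876)
Rajidae	Bathyraja maccaini Springer, 1971
Paralepididae	Notolepis coatsorum
Macrouridae	Macrourus caml McMillan, Iwamoto, Stewart & Smith, 2012
Macrouridae	Macrourus whitsoni
Macrouridae	Antimora rostrata (Günther, 1878)
Muraenolepididae	Muraenolepis marmorata Günther, 1880
Myctophidae	Electrona antarctica
Myctophidae	Gymnoscopelus braueri
Myctophidae	Gymnoscopelus nicholsi
Bathylagidae	Bathylagus sp.
Artedidraconidae	Artedidraco spp.
Artedidraconidae	Pogonophryne permitini Andriashev, 1967
Bathydraconidae	Cygnodraco mawsoni
Bathydraconidae	Gerlachea australis Dollo, 1900
Bathydraconidae	Prionodraco evansii
Bathydraconidae	Gymnodraco acuticeps Boulenger, 1902
Channichthyidae	Chaenodraco wilsoni Regan, 1914
Channichthyidae	Chionobathyscus dewitti
Channichthyidae	Cryodraco spp.
Nototheniidae	Lepidonotothen squamifrons (Günther, 1880)
Nototheniidae	Dissostichus mawsoni Norman, 1937
Nototheniidae	Pleuragramma antarctica
Nototheniidae	Trematomus brachysoma Pappenheim, 1912
Nototheniidae	Trematomus spp.
Zoarcidae	Lycodichthys spp.
Zoarcidae	Pachycara spp.
Liparidae	Paraliparis leobergi Andriashev, 1982
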