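family	species
Paralepididae	Notolepis coatsorum
Macrouridae	Coryphaenoides lecointei
Macrouridae	Macrourus whitsoni
Muraenolepididae	Muraenolepis orangiensis
Muraenolepididae	Notomuraenobathys microcephalus
Myctophidae	Electrona antarctica
Myctophidae	Gymnoscopelus braueri
Myctophidae	Gymnoscopelus nicholsi
Myctophidae	Gymnoscopelus opisthopterus
Bathylagidae	Bathylagus antarcticus
Artedidraconidae	Artedidraco shackletoni
Artedidraconidae	Artedidraco skottsbergi
Artedidraconidae	Pogonophryne scotti
Bathydraconidae	Cygnodraco mawsoni
Bathydraconidae	Bathydraco antarcticus
Bathydraconidae	Prionodraco evansii
Bathydraconidae	Racovitzia glacialis
Channichthyidae	Chionodraco hamatus
Channichthyidae	Chionobathyscus dewitti
Nototheniidae	Trematomus pennellii
Nototheniidae	Trematomus scotti
Zoarcidae	Lycodichthys antarcticus
Zoarcidae	Lycenchelys aratrirostris
Liparidae	Careproctus longipectoralis
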