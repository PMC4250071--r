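name,rank,parent,t_old,t_young
Phanerozoic,eon,,538.8,0
Paleozoic,era,Phanerozoic,538.8,251.902
Mesozoic,era,Phanerozoic,251.902,66
Cenozoic,era,Phanerozoic,66,0
Cambrian,period,Paleozoic,538.8,486.85
Ordovician,period,Paleozoic,486.85,443.1
Silurian,period,Paleozoic,443.1,419.62
Devonian,period,Paleozoic,419.62,358.86
Carboniferous,period,Paleozoic,358.86,298.9
Permian,period,Paleozoic,298.9,251.902
Triassic,period,Mesozoic,251.902,201.4
Jurassic,period,Mesozoic,201.4,143.1
Cretaceous,period,Mesozoic,143.1,66
Paleogene,period,Cenozoic,66,23.03
Neogene,period,Cenozoic,23.03,2.58
Quaternary,period,Cenozoic,2.58,0
Terreneuvian,epoch,Cambrian,538.8,521
Cambrian Series 2,epoch,Cambrian,521,509
Miaolingian,epoch,Cambrian,509,497
Furongian,epoch,Cambrian,497,486.85
Early Ordovician,epoch,Ordovician,486.85,470
Middle Ordovician,epoch,Ordovician,470,458.2
Late Ordovician,epoch,Ordovician,458.2,443.1
Llandovery,epoch,Silurian,443.1,432.9
Wenlock,epoch,Silurian,432.9,427
Ludlow,epoch,Silurian,427,423
Pridoli,epoch,Silurian,423,419.62
Early Devonian,epoch,Devonian,419.62,393.3
Middle Devonian,epoch,Devonian,393.3,382.7
Late Devonian,epoch,Devonian,382.7,358.86
Mississippian,epoch,Carboniferous,358.86,323.2
Pennsylvanian,epoch,Carboniferous,323.2,298.9
Cisuralian,epoch,Permian,298.9,273.01
Guadalupian,epoch,Permian,273.01,259.51
Lopingian,epoch,Permian,259.51,251.902
Early Triassic,epoch,Triassic,251.902,247.2
Middle Triassic,epoch,Triassic,247.2,237
Late Triassic,epoch,Triassic,237,201.4
Early Jurassic,epoch,Jurassic,201.4,174.7
Middle Jurassic,epoch,Jurassic,174.7,161.5
Late Jurassic,epoch,Jurassic,161.5,143.1
Early Cretaceous,epoch,Cretaceous,143.1,100.5
Late Cretaceous,epoch,Cretaceous,100.5,66
Paleocene,epoch,Paleogene,66,56
Eocene,epoch,Paleogene,56,33.9
Oligocene,epoch,Paleogene,33.9,23.03
Miocene,epoch,Neogene,23.03,5.333
Pliocene,epoch,Neogene,5.333,2.58
Pleistocene,epoch,Quaternary,2.58,0.0117
Holocene,epoch,Quaternary,0.0117,0
Fortunian,stage,Terreneuvian,538.8,529
Cambrian Stage 2,stage,Terreneuvian,529,521
Cambrian Stage 3,stage,Cambrian Series 2,521,514.5
Cambrian Stage 4,stage,Cambrian Series 2,514.5,509
Wuliuan,stage,Miaolingian,509,504.5
Drumian,stage,Miaolingian,504.5,500.5
Guzhangian,stage,Miaolingian,500.5,497
Paibian,stage,Furongian,497,494.2
Jiangshanian,stage,Furongian,494.2,491
Cambrian Stage 10,stage,Furongian,491,486.85
Tremadocian,stage,Early Ordovician,486.85,477.1
Floian,stage,Early Ordovician,477.1,470
Dapingian,stage,Middle Ordovician,470,467.3
Darriwilian,stage,Middle Ordovician,467.3,458.2
Sandbian,stage,Late Ordovician,458.2,452.8
Katian,stage,Late Ordovician,452.8,445.2
Hirnantian,stage,Late Ordovician,445.2,443.1
Rhuddanian,stage,Llandovery,443.1,440.5
Aeronian,stage,Llandovery,440.5,438.6
Telychian,stage,Llandovery,438.6,432.9
Sheinwoodian,stage,Wenlock,432.9,430.6
Homerian,stage,Wenlock,430.6,427
Gorstian,stage,Ludlow,427,425
Ludfordian,stage,Ludlow,425,423
Lochkovian,stage,Early Devonian,419.62,410.8
Pragian,stage,Early Devonian,410.8,407.6
Emsian,stage,Early Devonian,407.6,393.3
Eifelian,stage,Middle Devonian,393.3,387.7
Givetian,stage,Middle Devonian,387.7,382.7
Frasnian,stage,Late Devonian,382.7,372.2
Famennian,stage,Late Devonian,372.2,358.86
Tournaisian,stage,Mississippian,358.86,346.7
Visean,stage,Mississippian,346.7,330.9
Serpukhovian,stage,Mississippian,330.9,323.2
Bashkirian,stage,Pennsylvanian,323.2,315.2
Moscovian,stage,Pennsylvanian,315.2,307
Kasimovian,stage,Pennsylvanian,307,303.7
Gzhelian,stage,Pennsylvanian,303.7,298.9
Namurian,stage,Carboniferous,330.9,318.1
Asselian,stage,Cisuralian,298.9,293.52
Sakmarian,stage,Cisuralian,293.52,290.1
Artinskian,stage,Cisuralian,290.1,283.5
Kungurian,stage,Cisuralian,283.5,273.01
Roadian,stage,Guadalupian,273.01,266.9
Wordian,stage,Guadalupian,266.9,264.28
Capitanian,stage,Guadalupian,264.28,259.51
Wuchiapingian,stage,Lopingian,259.51,254.14
Changhsingian,stage,Lopingian,254.14,251.902
Induan,stage,Early Triassic,251.902,251.2
Olenekian,stage,Early Triassic,251.2,247.2
Anisian,stage,Middle Triassic,247.2,242
Ladinian,stage,Middle Triassic,242,237
Carnian,stage,Late Triassic,237,227
Norian,stage,Late Triassic,227,208.5
Rhaetian,stage,Late Triassic,208.5,201.4
Hettangian,stage,Early Jurassic,201.4,199.5
Sinemurian,stage,Early Jurassic,199.5,192.9
Pliensbachian,stage,Early Jurassic,192.9,184.2
Toarcian,stage,Early Jurassic,184.2,174.7
Aalenian,stage,Middle Jurassic,174.7,170.9
Bajocian,stage,Middle Jurassic,170.9,168.2
Bathonian,stage,Middle Jurassic,168.2,165.3
Callovian,stage,Middle Jurassic,165.3,161.5
Oxfordian,stage,Late Jurassic,161.5,154.8
Kimmeridgian,stage,Late Jurassic,154.8,149.2
Tithonian,stage,Late Jurassic,149.2,143.1
Berriasian,stage,Early Cretaceous,143.1,137.7
Valanginian,stage,Early Cretaceous,137.7,132.6
Hauterivian,stage,Early Cretaceous,132.6,125.77
Barremian,stage,Early Cretaceous,125.77,121.4
Aptian,stage,Early Cretaceous,121.4,113
Albian,stage,Early Cretaceous,113,100.5
Cenomanian,stage,Late Cretaceous,100.5,93.9
Turonian,stage,Late Cretaceous,93.9,89.8
Coniacian,stage,Late Cretaceous,89.8,86.3
Santonian,stage,Late Cretaceous,86.3,83.6
Campanian,stage,Late Cretaceous,83.6,72.1
Maastrichtian,stage,Late Cretaceous,72.1,66
Danian,stage,Paleocene,66,61.6
Selandian,stage,Paleocene,61.6,59.2
Thanetian,stage,Paleocene,59.2,56
Ypresian,stage,Eocene,56,47.8
Lutetian,stage,Eocene,47.8,41.2
Bartonian,stage,Eocene,41.2,37.71
Priabonian,stage,Eocene,37.71,33.9
Rupelian,stage,Oligocene,33.9,27.82
Chattian,stage,Oligocene,27.82,23.03
Aquitanian,stage,Miocene,23.03,20.44
Burdigalian,stage,Miocene,20.44,15.98
Langhian,stage,Miocene,15.98,13.82
Serravallian,stage,Miocene,13.82,11.63
Tortonian,stage,Miocene,11.63,7.246
Messinian,stage,Miocene,7.246,5.333
Zanclean,stage,Pliocene,5.333,3.6
Piacenzian,stage,Pliocene,3.6,2.58
Gelasian,stage,Pleistocene,2.58,1.8
Calabrian,stage,Pleistocene,1.8,0.774
Chibanian,stage,Pleistocene,0.774,0.129
Upper Pleistocene,stage,Pleistocene,0.129,0.0117
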