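class,order,family,species,n_photographs,rai_printed,occupancy,selected
Mammalia,Proboscidea,Elephantidae,Elephas maximus,307,74.6,50,TRUE
Mammalia,Artiodactyla,Cervidae,Rusa unicolor,731,91.0,61,TRUE
Mammalia,Artiodactyla,Cervidae,Muntiacus vaginalis,381,65.7,44,TRUE
Mammalia,Artiodactyla,Suidae,Sus scrofa,32,17.9,12,TRUE
Mammalia,Artiodactyla,Bovidae,Capricornis milneedwardsii,21,10.4,7,FALSE
Mammalia,Primates,Cercopithecidae,Macaca mulatta,80,32.8,22,TRUE
Mammalia,Primates,Cercopithecidae,Macaca leonina,21,13.4,9,TRUE
Mammalia,Primates,Cercopithecidae,Trachypithecus crepusculus,1,1.5,1,FALSE
Mammalia,Rodentia,Hystricidae,Atherurus macrourus,33,14.9,10,TRUE
Mammalia,Rodentia,Hystricidae,Hystrix brachyura subcristata,58,23.9,16,TRUE
Mammalia,Rodentia,Sciuridae,Callosciurus erythraeus,19,20.9,14,TRUE
Mammalia,Carnivora,Felidae,Prionailurus bengalensis,12,14.9,10,TRUE
Mammalia,Carnivora,Mustelidae,Melogale moschata,5,4.5,3,FALSE
Mammalia,Carnivora,Mustelidae,Martes flavigula,3,4.5,1,FALSE
Mammalia,Carnivora,Viverridae,Viverricula indica,5,3.0,2,FALSE
Mammalia,Carnivora,Viverridae,Paradoxurus hermaphroditus,8,4.5,3,FALSE
Mammalia,Carnivora,Viverridae,Paguma larvata,1,1.5,1,FALSE
Mammalia,Carnivora,Ursidae,Ursus thibetanus,2,1.5,1,FALSE
Aves,Galliformes,Phasianidae,Gallus gallus,101,18.0,12,TRUE
Aves,Galliformes,Phasianidae,Lophura nycthemera,11,9.0,6,FALSE
Aves,Galliformes,Phasianidae,Arborophila atrogularis,1,1.5,1,FALSE
Aves,Accipitriformes,Accipitridae,Pernis ptilorhynchus,1,1.5,1,FALSE
Aves,Accipitriformes,Accipitridae,Spilornis cheela,3,3.0,2,FALSE
Aves,Passeriformes,Sittidae,Sitta nagaensis,1,1.5,1,FALSE
Aves,Passeriformes,Sittidae,Sitta frontalis,1,1.5,1,FALSE
Aves,Passeriformes,Turdidae,Turdus dissimilis,13,10.4,1,FALSE
Aves,Passeriformes,Phylloscopidae,Phylloscopus tephrocephalus,1,1.5,1,FALSE
Aves,Passeriformes,Pellorneidae,Pellorneum ruficeps,3,4.5,3,FALSE
Aves,Passeriformes,Pellorneidae,Schoeniparus dubius,1,1.5,1,FALSE
Aves,Passeriformes,Timaliidae,Pomatorhinus schisticeps,1,1.5,1,FALSE
Aves,Passeriformes,Leiothrichidae,Leiothrix argentauris,1,1.5,1,FALSE
Aves,Passeriformes,Muscicapidae,Copsychus malabaricus,1,1.5,1,FALSE
Aves,Passeriformes,Muscicapidae,Copsychus saularis,2,1.5,1,FALSE
Aves,Passeriformes,Muscicapidae,Myophonus caeruleus,3,3.0,2,FALSE
Aves,Passeriformes,Pycnonotidae,Alophoixus flaveolus,1,1.5,1,FALSE
Aves,Passeriformes,Alcippeidae,Alcippe fratercula,1,1.5,1,FALSE
Aves,Columbiformes,Columbidae,Streptopelia decaocto,1,1.5,1,FALSE
Aves,Columbiformes,Columbidae,Chalcophaps indica,4,6.0,4,FALSE
Aves,Columbiformes,Columbidae,Macropygia unchall,2,1.5,1,FALSE
Aves,Piciformes,Picidae,Chrysophlegma flavinucha,1,1.5,1,FALSE
Aves,Coraciiformes,Meropidae,Nyctyornis athertoni,1,1.5,1,FALSE
Aves,Bucerotiformes,Bucerotidae,Anthracoceros albirostris,1,1.5,1,FALSE
Aves,Strigiformes,Strigidae,Glaucidium cuculoides,1,1.5,1,FALSE
Reptilia,Squamata,Varanidae,Varanus salvator,1,1.5,1,FALSE
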