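family,genus,species,functional_type,growth_form,n_individuals
Anacardiaceae,Choerospondias,axillaris,deciduous,tree,5
Anacardiaceae,Pistacia,chinensis,deciduous,tree,16
Anacardiaceae,Rhus,chinensis,deciduous,tree,9
Anacardiaceae,Rhus,punjabensis,deciduous,tree,1
Anacardiaceae,Toxicodendron,succedaneum,deciduous,tree,9
Aquifoliaceae,Ilex,chinensis,evergreen,tree,6
Aquifoliaceae,Ilex,szechwanensis,evergreen,shrub,10
Araliaceae,Aralia,chinensis,deciduous,shrub,5
Araliaceae,Kalopanax,pictus,deciduous,tree,6
Betulaceae,Betula,luminifera,deciduous,tree,8
Cornaceae,Cornus,controversa,deciduous,tree,5
Ebenaceae,Diospyros,kaki,deciduous,tree,1
Elaeocarpaceae,Elaeocarpus,japonicus,evergreen,tree,8
Euphorbiaceae,Mallotus,philippensis,deciduous,tree,5
Euphorbiaceae,Mallotus,tenuifolius,evergreen,tree,5
Fagaceae,Castanopsis,carlesii,evergreen,tree,4
Fagaceae,Castanopsis,fargesii,evergreen,tree,6
Fagaceae,Castanopsis,sp,evergreen,tree,4
Fagaceae,Cyclobalanopsis,glauca,evergreen,tree,14
Fagaceae,Lithocarpus,hancei,evergreen,tree,10
Fagaceae,Quercus,serrata,deciduous,tree,12
Fagaceae,Quercus,variabilis,deciduous,tree,11
Juglandaceae,Platycarya,strobilacea,deciduous,tree,6
Juglandaceae,Pterocarya,stenoptera,deciduous,tree,4
Lauraceae,Cinnamomm,bodinieri,evergreen,tree,8
Lauraceae,Lindera,communis,evergreen,shrub,5
Lauraceae,Machilus,pingii,evergreen,tree,5
Moraceae,Ficus,henryi,evergreen,shrub,5
Moraceae,Ficus,heterophylla,deciduous,tree,1
Myrsinaceae,Myrsine,africana,evergreen,shrub,8
Olacaceae,Schoepfia,jasminodora,deciduous,tree,2
Pittosporaceae,Pittosporum,podocarpum,evergreen,shrub,7
Pittosporaceae,Pittosporum,sp,evergreen,shrub,3
Rosaceae,Photinia,davidsoniae,evergreen,tree,5
Rosaceae,Pyracantha,fortuneana,evergreen,shrub,5
Rutaceae,Zanthoxylum,ovalifolium,deciduous,tree,6
Symplocaceae,Symplocos,anomala,deciduous,tree,5
Symplocaceae,Symplocos,cochinchinensis var laurina,evergreen,tree,10
Symplocaceae,Symplocos,paniculata,evergreen,tree,4
Symplocaceae,Symplocos,stellaris,evergreen,tree,8
Symplocaceae,Symplocos,sumuntia,evergreen,tree,10
Theaceae,Camellia,oleifera,evergreen,shrub,13
Theaceae,Eurya,alata,evergreen,shrub,6
Theaceae,Eurya,nitida,evergreen,shrub,7
Ulmaceae,Celtis,vardervoetiana,deciduous,tree,1
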