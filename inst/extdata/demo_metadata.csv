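genus,group,diet,isolated_only,molar_count
Arctocyon,Condylarthra,omnivorous,FALSE,3
Hyopsodus,Condylarthra,omnivorous,FALSE,3
Uintatherium,Artiodactyla,folivorous,FALSE,3
Didelphodus,Cimolesta,insectivorous,FALSE,3
Steropodon,Australosphenida,insectivorous,FALSE,3
Mesonyx,Acreodi,carnivorous,FALSE,3
Ptilodus,Multituberculata,omnivorous,TRUE,2
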