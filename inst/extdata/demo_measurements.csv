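specimen_id,genus,tooth,length,width,source
Arctocyon_1,Arctocyon,m1,14.2,10.1,literature
Arctocyon_1,Arctocyon,m2,16.8,12.4,literature
Arctocyon_1,Arctocyon,m3,15.1,10.9,literature
Arctocyon_2,Arctocyon,m1,13.9,9.8,literature
Arctocyon_2,Arctocyon,m2,16.2,12.1,literature
Arctocyon_2,Arctocyon,m3,14.8,10.6,literature
Hyopsodus_1,Hyopsodus,m1,4.1,3.0,photo
Hyopsodus_1,Hyopsodus,m2,4.4,3.4,photo
Hyopsodus_1,Hyopsodus,m3,4.9,3.5,photo
Uintatherium_1,Uintatherium,m1,28.0,20.5,literature
Uintatherium_1,Uintatherium,m2,38.5,27.0,literature
Uintatherium_1,Uintatherium,m3,49.0,31.5,literature
Didelphodus_1,Didelphodus,m1,3.6,2.6,photo
Didelphodus_1,Didelphodus,m2,3.4,2.5,photo
Didelphodus_1,Didelphodus,m3,3.0,,photo
Didelphodus_2,Didelphodus,m1,3.5,2.7,photo
Didelphodus_2,Didelphodus,m2,3.3,2.4,photo
Didelphodus_2,Didelphodus,m3,2.9,2.1,photo
Steropodon_1,Steropodon,m1,5.6,3.9,literature
Steropodon_1,Steropodon,m2,5.7,4.0,literature
Steropodon_1,Steropodon,m3,5.5,3.8,literature
Mesonyx_1,Mesonyx,m1,15.0,8.9,database
Mesonyx_1,Mesonyx,m3,14.1,8.2,database
Ptilodus_1,Ptilodus,m1,6.0,3.1,literature
Ptilodus_1,Ptilodus,m2,4.1,2.8,literature
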