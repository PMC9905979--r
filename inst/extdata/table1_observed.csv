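species,y2019,y2020,y2021,onshore,offshore,landings,n_tagged
garden_warbler,18,25,23,51,15,5,93
whitethroat,17,26,25,59,9,12,95
sedge_warbler,13,17,14,44,0,7,87
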