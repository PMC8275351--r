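{"block_id":"toy","sites":[{"site_id":"y1","position":101,"major":"A","minor":"G","public_maf":0.5},{"site_id":"y2","position":202,"major":"C","minor":"T","public_maf":0.25},{"site_id":"y3","position":303,"major":"G","minor":"A","public_maf":0.5},{"site_id":"y4","position":404,"major":"T","minor":"C","public_maf":0.5}],"haplotypes":[{"id":"x1","pattern":"1011","freq":0.5},{"id":"x2","pattern":"1001","freq":0.25},{"id":"x3","pattern":"0100","freq":0.25}]}
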