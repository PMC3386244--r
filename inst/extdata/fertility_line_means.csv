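line,role,mean,se,n_replicates
sim132,wildtype,289,82.4,10
25H,introgression,NA,NA,NA
78P,introgression,324,74.8,10
6H,introgression,313,58.8,10
62P,introgression,334,76.3,10
29P,introgression,329,39.7,10
94P,introgression,214,30.8,10
28H,introgression,211,65.6,10
12H,introgression,263,84.8,10
60H,introgression,339,36.4,10
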