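class,n,n_negative,n_placebo,n_active,n_female,n_apoe4,n_cdr_progressor
stable,1257,481,386,390,763,525,287
slow,253,35,128,90,136,160,182
fast,119,3,49,67,82,88,105
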