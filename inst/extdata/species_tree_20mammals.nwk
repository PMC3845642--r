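(Oa:220,(Md:190,(La:105,(((Cj:43,(Mmu:29,(Nl:20,(Pp:16,(Gg:9,(Hs:7,Pt:7):2):7):4):9):14):47,(Oc:82,((Mm:18,Rn:18):55,(Hg:41,Cp:41):32):9):8):4,(Ml:82,(Bt:78,(Ec:74,(Cf:45,Am:45):29):4):4):12):11):85):30);
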