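id,kind,structure,carbon_count,label,salt_form
amine-1,amine,NCCCN(C)C,5,3-(dimethylamino)-1-propylamine,FALSE
amine-11,amine,NCCN1CCCC1,6,1-(2-aminoethyl)pyrrolidine,FALSE
epoxide-6,epoxide,CCCCC1CO1,6,"1,2-epoxyhexane",FALSE
epoxide-8,epoxide,CCCCCCC1CO1,8,"1,2-epoxyoctane",FALSE
epoxide-10,epoxide,CCCCCCCCC1CO1,10,"1,2-epoxydecane",FALSE
epoxide-12,epoxide,CCCCCCCCCCC1CO1,12,"1,2-epoxydodecane",FALSE
epoxide-14,epoxide,CCCCCCCCCCCCC1CO1,14,"1,2-epoxytetradecane",FALSE
acyl-6,acyl_chloride,CCCCCC(=O)Cl,6,hexanoyl chloride,FALSE
acyl-8,acyl_chloride,CCCCCCCC(=O)Cl,8,octanoyl chloride,FALSE
acyl-10,acyl_chloride,CCCCCCCCCC(=O)Cl,10,decanoyl chloride,FALSE
acyl-12,acyl_chloride,CCCCCCCCCCCC(=O)Cl,12,dodecanoyl chloride,FALSE
acyl-14,acyl_chloride,CCCCCCCCCCCCCC(=O)Cl,14,tetradecanoyl chloride,FALSE
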