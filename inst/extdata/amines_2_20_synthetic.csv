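id,kind,structure,carbon_count,label,salt_form
amine-2,amine,CCCCN,4,n-butylamine (synthetic stand-in; primary monoamine class),FALSE
amine-3,amine,COCCN,3,2-methoxyethylamine (synthetic stand-in; primary monoamine class),FALSE
amine-4,amine,NN(C)C,2,"1,1-dimethylhydrazine (synthetic stand-in; hydrazine class)",FALSE
amine-5,amine,NN1CCCC1,4,1-aminopyrrolidine (synthetic stand-in; hydrazine class),FALSE
amine-6,amine,CCCCCCN,6,n-hexylamine (synthetic stand-in; primary monoamine class),FALSE
amine-7,amine,NCCN(C)C,4,"N,N-dimethylethylenediamine (synthetic stand-in; dimethylamino, 2-carbon spacer)",FALSE
amine-8,amine,NCCCCN(C)C,6,"N,N-dimethyl-1,4-butanediamine (synthetic stand-in; dimethylamino, 4-carbon spacer)",FALSE
amine-9,amine,CCN(CC)CCN,6,"N,N-diethylethylenediamine (synthetic stand-in; diethylamino, 2-carbon spacer)",FALSE
amine-10,amine,CCN(CC)CCCN,7,"N,N-diethyl-1,3-propanediamine (synthetic stand-in; diethylamino, 3-carbon spacer)",FALSE
amine-12,amine,NCCCN1CCCC1,7,"1-(3-aminopropyl)pyrrolidine (synthetic stand-in; pyrrolidinyl, 3-carbon spacer)",FALSE
amine-13,amine,NCCN(C)CCN(C)C,7,"N-(2-aminoethyl)-N,N',N'-trimethylethylenediamine (synthetic stand-in; polyamine class)",FALSE
amine-14,amine,CC(C)N(C(C)C)CCN,8,"N,N-diisopropylethylenediamine (synthetic stand-in; non-ideal tertiary amine form)",FALSE
amine-15,amine,CCN(C)CCN,5,"N-ethyl-N-methylethylenediamine (synthetic stand-in; non-ideal tertiary amine form)",FALSE
amine-16,amine,CNCCNC,4,"N,N'-dimethylethylenediamine (synthetic stand-in; di-secondary diamine class)",FALSE
amine-17,amine,CCNCCNCC,6,"N,N'-diethylethylenediamine (synthetic stand-in; di-secondary diamine class)",FALSE
amine-18,amine,CNCCCNC,5,"N,N'-dimethyl-1,3-propanediamine (synthetic stand-in; di-secondary diamine class)",FALSE
amine-19,amine,C1CNCCN1,4,piperazine (synthetic stand-in; di-secondary diamine class),FALSE
amine-20,amine,C1CNCCNC1,5,"1,4-diazepane (synthetic stand-in; di-secondary diamine class)",FALSE
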