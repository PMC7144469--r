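record_id,molecule_chembl_id,canonical_smiles,standard_type,standard_relation,standard_value,standard_units,organism
r01,CHEMBL139089,CCOc1ccccc1,Ki,=,37,nM,Homo sapiens
r02,CHEMBL139089,CCOc1ccccc1,Ki,=,68.2,nM,Homo sapiens
r03,CHEMBL317433,CCN(CC)CCO,Ki,=,0.2,nM,Homo sapiens
r04,TOY003,c1ccncc1,IC50,=,100,nM,Homo sapiens
r05,TOY004,CC(C)O,Ki,=,1,µM,Homo sapiens
r06,TOY005,CCCCN,pKi,=,9,,Homo sapiens
r07,TOY006,CCCCO,pIC50,=,7,,Homo sapiens
r08,TOY007,CCNCC,Ki,<,10,nM,Homo sapiens
r09,TOY007,CCNCC,Ki,>,1000,nM,Homo sapiens
r10,TOY008,CCCC,IC50,~,50,nM,Homo sapiens
r11,TOY009,CCOCC,Ki,=,5,pM,Homo sapiens
r12,TOY009,CCOCC,Ki,=,2,fM,Homo sapiens
r13,TOY010,CCSCC,Ki,=,3,mM,Homo sapiens
r14,TOY010,CCSCC,Ki,=,4,M,Homo sapiens
r15,TOY011,CNC,Kd,=,12,nM,Homo sapiens
r16,TOY011,CNC,EC50,=,8,nM,Homo sapiens
r17,TOY012,COC,Ki,=,7,µg.mL-1,Homo sapiens
r18,TOY013,CCC,log(Ki),=,1.5,,Homo sapiens
r19,TOY014,CC,Ki,=,-5,nM,Homo sapiens
r20,TOY015,C,Ki,=,150,nM,Rattus norvegicus
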