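# Adenylate kinase (E. coli) domain annotation, author numbering of 4AKE
# chain A. Boundaries follow the commonly used CORE / NMP-binding / LID
# division of the enzyme; adjust to taste, the file is an example input
# for classify_interdomain()/run_pipeline().
domain,start,end
CORE,1,29
NMP_bind,30,59
CORE,60,121
LID,122,159
CORE,160,214
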