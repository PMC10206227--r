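synonym	drug
zocor	simvastatin
sinvastatina	simvastatin
prilosec	omeprazole
losec	omeprazole
omeprazol	omeprazole
coumadin	warfarin
marevan	warfarin
varfarina	warfarin
elavil	amitriptyline
amitriptilina	amitriptyline
zoloft	sertraline
sertralina	sertraline
advil	ibuprofen
motrin	ibuprofen
ibuprofeno	ibuprofen
plavix	clopidogrel
clopidogrel bisulfate	clopidogrel
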