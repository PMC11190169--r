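verbatim	ingredient
mounjaro	tirzepatide
zepbound	tirzepatide
tirzepatide	tirzepatide
ozempic	semaglutide
wegovy	semaglutide
rybelsus	semaglutide
victoza	liraglutide
saxenda	liraglutide
trulicity	dulaglutide
byetta	exenatide
bydureon	exenatide
glucophage	metformin
glucophage xr	metformin
metformin hydrochloride	metformin
lantus	insulin glargine
basaglar	insulin glargine
jardiance	empagliflozin
farxiga	dapagliflozin
januvia	sitagliptin
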