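substrate	product	ec	pathway
glucose	glucose-6-phosphate	2.7.1.1	glycolysis
glucose-6-phosphate	fructose-6-phosphate	5.3.1.9	glycolysis
fructose-6-phosphate	3-phosphoglycerate	2.7.1.11	glycolysis
3-phosphoglycerate	phosphoenolpyruvate	5.4.2.11	glycolysis
phosphoenolpyruvate	pyruvate	2.7.1.40	glycolysis
pyruvate	lactate	1.1.1.27	glycolysis
pyruvate	alanine	2.6.1.2	glycolysis
pyruvate	citrate	2.3.3.1	tca_cycle
citrate	cis-aconitate	4.2.1.3	tca_cycle
cis-aconitate	isocitrate	4.2.1.3	tca_cycle
isocitrate	2-oxoglutarate	1.1.1.41	tca_cycle
2-oxoglutarate	succinate	1.2.4.2	tca_cycle
succinate	fumarate	1.3.5.1	tca_cycle
fumarate	malate	4.2.1.2	tca_cycle
ornithine	citrulline	2.1.3.3	urea_cycle
citrulline	argininosuccinate	6.3.4.5	urea_cycle
argininosuccinate	arginine	4.3.2.1	urea_cycle
arginine	ornithine	3.5.3.1	urea_cycle
arginine	urea	3.5.3.1	urea_cycle
glutamine	glutamate	3.5.1.2	glutamine_metabolism
glutamate	glutamine	6.3.1.2	glutamine_metabolism
glutamate	2-oxoglutarate	1.4.1.3	glutamine_metabolism
glutamate	GABA	4.1.1.15	gaba_shunt
GABA	succinate	2.6.1.19	gaba_shunt
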