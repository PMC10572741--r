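label	role_group	name_patterns	product_patterns
ecfA	FAD transport	ecfA|ecfA1	energy-coupling factor transporter ATP-binding protein EcfA1?\b|ECF transporter ATP-binding protein A\b
ecfA'	FAD transport	ecfA'|ecfA2	energy-coupling factor transporter ATP-binding protein EcfA2|ECF transporter ATP-binding protein A2
fmnA	FAD transport	fmnA	FAD transporter (subunit|protein)|flavin adenine dinucleotide transporter
apbE/fmnB	FAD transport	apbE|fmnB	FAD:protein FMN transferase|flavin transferase ApbE
eetA	electron transfer	eetA	extracellular electron transfer (flavo)?protein EetA
eetB	electron transfer	eetB	extracellular electron transfer (flavo)?protein EetB
ndh2	electron transfer	ndh2|ndh-2|ndh	type.?(II|2) NADH( |:quinone )(dehydrogenase|oxidoreductase)|NADH dehydrogenase Ndh2?\b
pplA	electron transfer	pplA	peptide.pheromone.encoding lipoprotein|FMN.binding extracellular lipoprotein|FMNylated (extracellular )?(lipo)?protein
frdA-like	electron transfer	frdA	fumarate reductase( |, )flavoprotein( subunit)?
dmkA	DMK synthesis	dmkA|menA	1,4-dihydroxy-2-naphthoate (octa|poly|hepta)?prenyltransferase|demethylmenaquinone.*prenyltransferase
dmkB	DMK synthesis	dmkB|hepT	hepta?prenyl diphosphate synthase( component)?|polyprenyl.diphosphate synthase
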