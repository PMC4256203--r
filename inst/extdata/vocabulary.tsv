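keyword	class	subfamily
transposase	Transposable element	DNA transposon
reverse transcriptase	Transposable element	Retrotransposon
retrotransposon	Transposable element	Retrotransposon
transposon	Transposable element	DNA transposon
gag-pol	Transposable element	Retrotransposon
rna-directed dna polymerase	Transposable element	Retrotransposon
nonstructural protein	Viral	Virus
rna-dependent rna polymerase	Viral	Virus
capsid	Viral	Virus
virus	Viral	Virus
viral	Viral	Virus
lipocalin	Secreted	Lipocalin
triabin	Secreted	Lipocalin
pallidipin	Secreted	Lipocalin
procalin	Secreted	Lipocalin
nitrophorin	Secreted	Lipocalin
trialysin	Secreted	Trialysin
apyrase	Secreted	Apyrase
5' nucleotidase	Secreted	Apyrase
antigen 5	Secreted	Antigen 5 family
kazal	Secreted	Protease inhibitor
pacifastin	Secreted	Protease inhibitor
serpin	Secreted	Protease inhibitor
metalloprotease	Secreted	Protease
cathepsin	Secreted	Protease
asparaginyl peptidase	Secreted	Protease
trypsin	Secreted	Protease
serine protease	Secreted	Protease
inositol phosphate phosphatase	Secreted	Enzyme
odorant binding	Secreted	Odorant/pheromone-binding proteins
pheromone binding	Secreted	Odorant/pheromone-binding proteins
defensin	Secreted	Antimicrobial peptide
diptericin	Secreted	Antimicrobial peptide
attacin	Secreted	Antimicrobial peptide
lysozyme	Secreted	Antimicrobial peptide
ggy	Secreted	GGY family
c-type lectin	Secreted	C-type lectin
mucin	Secreted	Mucin
salivary secreted	Secreted	Other secreted
ribosomal protein	Housekeeping	Protein synthesis
elongation factor	Housekeeping	Protein synthesis
collagen	Housekeeping	Extracellular matrix
cuticle	Housekeeping	Extracellular matrix
laminin	Housekeeping	Extracellular matrix
vitellogenin	Housekeeping	Storage
hexamerin	Housekeeping	Storage
tubulin	Housekeeping	Cytoskeletal
actin	Housekeeping	Cytoskeletal
myosin	Housekeeping	Cytoskeletal
ubiquitin	Housekeeping	Protein modification
heat shock	Housekeeping	Protein modification
methyltransferase	Housekeeping	Protein modification
proteasome	Housekeeping	Proteasome machinery
histone	Housekeeping	Nuclear regulation
cytochrome p450	Housekeeping	Detoxification
glutathione	Housekeeping	Detoxification
cytochrome c oxidase	Housekeeping	Metabolism
dehydrogenase	Housekeeping	Metabolism
juvenile hormone	Housekeeping	Metabolism
kinase	Housekeeping	Signal transduction
phosphatase	Housekeeping	Signal transduction
transporter	Housekeeping	Transporters
ion channel	Housekeeping	Transporters
transcription factor	Housekeeping	Transcription factor
doublesex	Housekeeping	Transcription factor
rna polymerase	Housekeeping	Transcription machinery
helicase	Housekeeping	Transcription machinery
exportin	Housekeeping	Protein export
signal peptidase	Housekeeping	Protein export
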