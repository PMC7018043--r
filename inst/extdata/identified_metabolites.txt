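3-(3-hydroxyphenyl)propionic acid
3-(4-hydroxyphenyl)propionic acid
3-aminoisobutyric acid
3-hydroxy-3-methylglutaric acid
3-phosphoglycerate
3,4-dihydroxycinnamic acid
3,4-dihydroxyhydrocinnamic acid NIST
3,4-dihydroxyphenylacetic acid
4-hydroxybenzoate
4-hydroxybutyric acid
4-hydroxycinnamic acid
4-hydroxyhippuric acid NIST
4-hydroxyphenylacetic acid
5-hydroxy-3-indoleacetic acid
aconitic acid
adenosine
alanine
allantoic acid
alpha-ketoglutarate
benzoic acid
benzylalcohol
beta-alanine
beta-gentiobiose
catechol
citramalic acid
citric acid
citrulline
conduritol-beta-expoxide
creatinine
deoxypentitol
erythritol
ferulic acid
fructose
fucose
galactinol
galactonic acid
gluconic acid
glyceric acid
glycerol
glycerol-3-galactoside
glycine
glycocyamine
glycolic acid
hexadecane
hexitol
hexuronic acid
hippuric acid
hydroxylamine
indole-3-acetate
indoxyl sulfate
inosine
isocitric acid
isohexonic acid
isomaltose
isoribose
isothreonic acid
kynurenic acid
lactic acid
lysine
lyxitol
lyxose
malic acid
mannose
mucic acid
myo-inositol
myristic acid
n-acetyl-d-hexosamine
N-acetylaspartic acid
N-acetylglutamate
N-acetylmannosamine
ornithine
oxalic acid
oxoproline
palmitic acid
pelargonic acid
pentitol
phenaceturic acid
phenol
phosphate
pimelic acid
pinitol
propane-1,3-diol NIST
pseudo uridine
putrescine
pyruvic acid
quinic acid
raffinose
ribitol
ribonic acid
ribose
saccharic acid
serine
sorbitol
stearic acid
succinic acid
sucrose
sulfuric acid
tagatose
taurine
threitol
threonic acid
trehalose
tryptophan
tyrosine
tyrosol
urea
uric acid
uridine
valine
vanillic acid
xylitol
xylonic acid
xylose
xylulose NIST
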