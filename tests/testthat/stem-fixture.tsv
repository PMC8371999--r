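word	stem
abb	abb
aggravate	aggrav
analyseser	analyses
analysesfulness	analyses
analysisational	analysis
analysiser	analysis
andes	andes
angularityible	angularity
angularityousli	angularity
anxiousion	anxious
archaeologyfulli	archaeology
arsenicabli	arsenic
arsenicful	arsenic
atlasfulness	atlas
atlasied	atlasi
authorizedness	authorized
beautifulfulli	beautiful
beautifullessli	beautifulless
beautifully	beauti
biasbli	biasbl
bleedingally	bleeding
bleedingfulli	bleeding
bleveiu	bleveiu
blindnessousli	blindness
bovineation	bovin
caressaliti	caress
caressbiliti	caressbl
caressment	caress
caresss	caresss
circulate	circul
circulatorybiliti	circulatorybl
clotted	clot
clotting	clot
conditional	condit
corporationentli	corporation
criedousness	criedous
curiouslyies	curiouslyi
curiouslysses	curiouslyss
decisive	decis
dependable	depend
destroyerbli	destroyerbl
destroyerli	destroy
destroyerousness	destroyer
destructioner	destruction
deteriorate	deterior
dfldiwhz	dfldiwhz
diagnosealism	diagnos
diagnoseizer	diagnos
die	die
dizzyism	dizzyism
dmgmle	dmgmle
effective	effect
effectivelyation	effectively
enjoyingingly	enjoying
enjoys	enjoy
enrolled	enrol
exacerbateabli	exacerbat
exacerbateate	exacerbat
exacerbateiveness	exacerbat
exacerbationies	exacerbationi
exhibit	exhibit
exhibitabli	exhibit
fatigueically	fatigu
fbidrsvt	fbidrsvt
febaddw	febaddw
feline	felin
fofy	fofi
formation	format
freedomied	freedomi
frheza	frheza
gfmgomwho	gfmgomwho
goodnesseed	goodnesse
goodnessousli	goodness
gormandizeentli	gormandiz
hemorrhagingsses	hemorrhagingss
heroicaliti	heroic
heroicallyate	heroically
heroicallyer	heroically
heroicallysses	heroicallyss
heroied	heroi
hiozipzfs	hiozipzf
homologous	homolog
hopeful	hope
hypnosisent	hypnosis
hypnotic	hypnot
immune	immun
influenza	influenza
informationaledly	inform
informationalli	inform
informationalment	informational
inhibition	inhibit
itchent	itchent
itchizer	itchiz
iublln	iublln
lactationaliti	lactat
legislator	legisl
lmfisdmrs	lmfisdmr
luxuriateeed	luxuriatee
man	man
menstrual	menstrual
messeseedly	messese
messyational	messyat
metastasizeeed	metastasizee
metastatical	metastat
national	nation
nationalbli	nationalbl
nationalism	nation
nationals	nation
neededation	needed
neededousness	needed
needsses	needss
oahpvvyp	oahpvvyp
oryye	oryy
panicate	panic
pizzaanci	pizzaanc
pizzaentli	pizzaent
plaster	plaster
plasterate	plaster
plasterfulness	plaster
pmcrazff	pmcrazff
political	polit
ponyanci	ponyanc
prescription	prescript
psoriasisal	psoriasis
ratedfulness	rated
ratingingly	rating
ratingizer	rating
referring	refer
referringalism	referring
referringive	referring
rehabilitationism	rehabilitation
rehabilitationous	rehabilitation
replacementic	replacement
rivmlibwy	rivmlibwi
rwvhy	rwvhi
say	say
sensitivityiveness	sensitivity
ski	ski
skisator	skisat
skisenci	skisenc
soothingabli	soothing
spasmtional	spasmtion
stayant	stayant
stayible	stayibl
stayically	stayic
sterile	steril
syncopeator	syncop
syncopeible	syncop
tabusedly	tabus
tabuser	tabus
tannedingly	tanned
tel	tel
terribly	terribl
terriblyation	terribly
terriblys	terribl
tiedation	tiedat
triplicateal	triplicat
triplicateli	triplic
ulceratebli	ulceratebl
ulcerationabli	ulceration
ulcerationism	ulceration
vfsi	vfsi
vmeagiuya	vmeagiuya
woman	woman
worryies	worryi
worrysses	worryss
woymaso	woymaso
yearly	year
yhuihbfnn	yhuihbfnn
yodelate	yodel
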