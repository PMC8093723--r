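family	species	shallow	deep	iucn
Ginglymostomatidae	Ginglymostoma cirratum	0	5	VU
Dasyatidae	Hypanus berthalutzae	0	2
Dasyatidae	Hypanus sp	0	1
Muraenidae	Gymnothorax funebris	1	5
Muraenidae	Muraena pavonina	2	1
Ophichthidae	Myrichthys ocellatus	1	1
Fistulariidae	Fistularia tabacaria	1	0
Scorpaenidae	Scorpaena plumieri	0	1
Holocentridae	Holocentrus adscensionis	22	211
Holocentridae	Myripristis jacobus	0	64
Serranidae	Alphestes afer	3	2
Serranidae	Cephalopholis fulva	14	68
Serranidae	Epinephelus adscensionis	1	11
Serranidae	Mycteroperca bonaci	0	2	VU
Serranidae	Paranthias furcifer	0	38
Serranidae	Rypticus saponaceus	1	2
Malacanthidae	Malacanthus plumieri	0	5
Echeneidae	Echeneis naucrates	2	0
Carangidae	Caranx bartholomaei	0	129
Carangidae	Caranx latus	3	0
Carangidae	Caranx lugubris	0	2
Carangidae	Elagatis bipinnulata	0	13
Carangidae	Pseudocaranx dentex	0	2
Carangidae	Selar crumenophthalmus	0	57
Lutjanidae	Lutjanus alexandrei	20	90
Lutjanidae	Lutjanus cf. apodus	1	3
Lutjanidae	Lutjanus jocu	4	37
Lutjanidae	Lutjanus synagris	0	5
Lutjanidae	Ocyurus chrysurus	0	63
Haemulidae	Anisotremus moricandi	5	0
Haemulidae	Anisotremus surinamensis	0	7
Haemulidae	Anisotremus virginicus	15	26
Haemulidae	Haemulon aurolineatum	46	73
Haemulidae	Haemulon parra	3	14
Haemulidae	Haemulon plumierii	6	21
Haemulidae	Haemulon squamipinna	337	560
Sparidae	Calamus pennatula	0	1
Sciaenidae	Equetus lanceolatus	0	1
Sciaenidae	Odontoscion dentex	3	9
Sciaenidae	Pareques acuminatus	4	68
Mullidae	Mulloidichthys martinicus	2	682
Mullidae	Pseudupeneus maculatus	5	43
Pempheridae	Pempheris schomburgkii	14	0
Chaetodontidae	Chaetodon ocellatus	0	7
Chaetodontidae	Chaetodon striatus	5	5
Pomacanthidae	Holacanthus ciliaris	5	13
Pomacanthidae	Holacanthus tricolor	1	23
Pomacanthidae	Pomacanthus paru	3	10
Kyphosidae	Kyphosus incisor	0	229
Cirrhitidae	Amblycirrhitus pinos	1	6
Pomacentridae	Abudefduf saxatilis	15	47
Pomacentridae	Chromis multilineata	8	27
Pomacentridae	Stegastes fuscus	12	0
Pomacentridae	Stegastes pictus	0	25
Pomacentridae	Stegastes variabilis	2	0
Sphyraenidae	Sphyraena barracuda	0	16
Labridae	Bodianus rufus	7	38
Labridae	Clepticus brasiliensis	0	6
Labridae	Halichoeres brasiliensis	5	4
Labridae	Halichoeres dimidiatus	3	21
Labridae	Halichoeres penrosei	1	0
Labridae	Halichoeres poeyi	9	14
Labridae	Thalassoma noronhanum	1	47
Labridae	Xyrichtys martinicensis	5	0
Labridae: Scarinae	Cryptotomus roseus	1	0
Labridae: Scarinae	Scarus trispinosus	1	5	EN
Labridae: Scarinae	Scarus zelindae	1	7	VU
Labridae: Scarinae	Sparisoma amplum	0	1
Labridae: Scarinae	Sparisoma axillare	24	20	VU
Labridae: Scarinae	Sparisoma frondosum	5	10	VU
Opistognathidae	Opistognathus sp	0	2
Labrisomidae	Labrisomus nuchipinnis	3	0
Blenniidae	Ophioblennius trinitatis	2	0
Gobiidae	Elacatinus figaro	6	16	VU
Microdesmidae	Ptereleotris randalli	2	0
Acanthuridae	Acanthurus bahianus	27	16
Acanthuridae	Acanthurus chirurgus	42	93
Acanthuridae	Acanthurus coeruleus	11	40
Scombridae	Scomberomorus regalis	0	1
Balistidae	Balistes vetula	1	0
Monacanthidae	Cantherhines macrocerus	0	11
Monacanthidae	Cantherhines pullus	0	4
Ostraciidae	Acanthostracion polygonius	1	0
Tetraodontidae	Canthigaster figueiredoi	0	4
Tetraodontidae	Sphoeroides spengleri	1	1
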