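species	n	matK	rbcL	nrITS2	combined	gap
Ac. sahniana	3	+	+	+	+	1
Af. dawei	1	-	-	-	-	0
Af. falcatus	2	-	-	-	-	0
Af. gracilior	2	-	-	+	+	0
Af. mannii	2	-	-	-	+	0
Af. usambarensis	1	-	-	-	-	0
Dc. compactus	1	-	-	-	-	0
Dc. dacrydioides	2	+	+	+	+	1
Dc. expansus	1	-	-	-	-	0
Dc. imbricatus	3	-	-	+	+	0
Dc. kinabaluensis	2	-	-	-	+	0
Dd. balansae	1	-	-	-	-	0
Dd. beccarii	1	-	+	+	+	1
Dd. cupressinum	2	+	-	+	+	1
Dd. elatum	1	+	+	+	+	1
Dd. guillauminii	3	-	-	-	-	0
Dd. ×suprinii	1	-	-	-	-	0
F. papuanum	1	+	+	+	+	1
F. taxioides	1	+	+	+	+	1
La. franklinii	2	+	+	+	+	1
Le. intermedius	1	+	+	+	+	1
Ma. colensoi	1	+	-	+	+	1
Mi. tetragona	2	+	+	+	+	1
N. fleuryi	1	+	+	+	+	1
N. formosensis	1	-	-	-	-	0
N. nagi	2	-	-	-	-	0
N. wallichiana	3	+	-	+	+	1
Ph. fitzgeraldii	2	+	+	+	+	1
Po. acutifolius	2	-	-	-	-	0
Po. affinis	1	-	+	+	+	1
Po. alpinus	2	-	-	-	-	0
Po. angustifolius	1	-	-	-	-	0
Po. archboldii	1	+	-	-	+	1
Po. assamica	1	-	-	-	-	0
Po. bracteatus	1	-	-	-	+	1
Po. brassii	2	-	-	-	+	1
Po. celatus	1	-	-	-	+	1
Po. chinensis	1	-	-	-	-	0
Po. chingianus	1	-	-	-	-	0
Po. coriaceus	2	-	-	-	-	0
Po. costalis	1	-	-	-	-	0
Po. cunninghamii	1	-	-	-	-	0
Po. degeneri	1	-	-	-	-	0
Po. dispermus	1	+	+	+	+	1
Po. drouynianus	1	-	+	-	+	1
Po. elatus	2	+	+	+	+	1
Po. elongatus	1	+	+	-	+	1
Po. fasciculus	1	-	-	-	-	0
Po. forrestii	1	-	-	-	-	0
Po. gnidioides	1	+	-	+	+	1
Po. grayae	1	+	-	+	+	1
Po. guatemalensis	3	-	-	-	-	0
Po. hallii	2	-	-	-	-	0
Po. henkelii	3	-	-	-	-	0
Po. lambertii	3	+	+	+	+	1
Po. latifolius	2	-	-	-	-	0
Po. lawrencii	2	-	-	-	-	0
Po. ledermannii	1	-	-	-	-	0
Po. longifoliolatus	2	-	-	-	+	1
Po. lucienii	2	-	-	-	-	0
Po. macrophyllus	3	-	-	-	-	0
Po. madagascariensis	1	+	+	+	+	1
Po. matudae	2	-	-	-	-	0
Po. milanjianus	1	-	-	-	-	0
Po. neriifolius	2	-	-	-	-	0
Po. nivalis	2	-	+	-	+	1
Po. novae-caledoniae	3	-	-	-	+	1
Po. nubigenus	1	-	+	+	+	1
Po. oleifolius	2	-	-	-	-	0
Po. pallidus	1	-	-	-	-	0
Po. parlatorei	2	-	-	+	+	1
Po. pilgeri	2	-	+	-	+	1
Po. polystachyus	2	-	-	-	+	0
Po. purdieanus	1	+	+	+	+	1
Po. ramosii	1	-	-	-	+	1
Po. rubens	2	-	-	-	-	0
Po. rumphii	2	-	-	+	+	1
Po. salignus	3	-	-	-	-	0
Po. sellowii	3	+	-	-	+	1
Po. smithii	1	+	+	+	+	1
Po. spinolosus	3	-	-	+	+	1
Po. sprucei	1	-	-	-	+	1
Po. subtropicalis	1	-	-	-	-	0
Po. sylvestris	3	-	-	-	-	0
Po. thailandensis	1	-	-	-	-	0
Po. totara	3	-	-	-	-	0
Po. urbanii	1	+	-	+	+	1
Pr. amara	2	+	+	+	+	1
Pr. andina	1	+	-	+	+	1
Pr. ferruginea	1	-	-	-	-	0
Pr. ferruginoides	1	-	-	+	+	0
Pr. ladei	2	+	+	+	+	1
Pr. taxifolia	2	+	+	+	+	1
R. comptonii	1	+	-	-	+	1
R. minus	1	-	-	+	+	1
R. rospigliosii	2	+	+	-	+	1
S. conspicua	2	+	+	+	+	1
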