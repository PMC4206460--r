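accession	name	residue	position	kinases
P31946	14-3-3 protein beta/alpha	T	207	No
P62258	14-3-3 protein epsilon	T	208	PLK2/PLK3
P63104	14-3-3 protein zeta/delta	T	205	No
Q02952	A-kinase anchor protein 12	S	381	No
Q9H4A4	Aminopeptidase B	T	408	No
Q9Y2X7	ARF GTPase-activating protein GIT1	S	643	No
Q07021	Complement component 1 Q subcomponent-binding protein	S	201	No
Q14566	DNA replication licensing factor MCM6	S	762	No
P55265	Double-stranded RNA-specific adenosine deaminase	S	481	No
P24534	Elongation factor 1-beta	S	95	No
P14625;P08238	Endoplasmin/Heat shock protein HSP 90-beta	S	106/45	No
Q9H501	ESF1 homolog	S	663	No
P55884	Eukaryotic translation initiation factor 3 subunit B	S	152	No
P56537	Eukaryotic translation initiation factor 6	S	175	CK1delta
P35269	General transcription factor IIF subunit 1	S	218	No
O60763	General vesicular transport factor p115	S	942	CK2/GCK
P08238	Heat shock protein HSP 90-beta	S	365	No
P51858	Hepatoma-derived growth factor	T	225	No
P31943;P55795	hnRNP H1/hnRNP H2	S	63	No
P17096	High mobility group protein HMG-I/HMG-Y	S	99	No
P46821	Microtubule-associated protein 1B	S	1156	No
Q14978	Nucleolar and coiled-body phosphoprotein 1	S	637	No
Q9NR30	Nucleolar RNA helicase 2	S	84	No
Q9NR30	Nucleolar RNA helicase 2	S	121	No
P19338	Nucleolin	S	28	No
P09874	Poly [ADP-ribose] polymerase 1	S	785	No
Q99623	Prohibitin-2	S	119	No
Q15185	Prostaglandin E synthase 3	S	113	CK2
Q15084	Protein disulfide-isomerase A6	S	428	CK2
P13521	Secretogranin-2	S	104	No
Q13813	Spectrin alpha chain, non-erythrocytic 1	S	391	No
Q96I25	Splicing factor 45	T	224	No
Q13428	Treacle protein	S	270	No
P40939	Trifunctional enzyme subunit alpha, mitochondrial	S	669	No
P60174	Triosephosphate isomerase	S	260	No
G3V1U9;P68363	Tubulin alpha-1A chain/Tubulin alpha-1B chain	S	48	No
Q9BVA1;Q13509;P07437	Tubulin beta-2B/Tubulin beta-3/Tubulin beta	T	72	No
P68371;P07437	Tubulin beta-4B chain/Tubulin beta chain	S	126	No
P15374	Ubiquitin carboxyl-terminal hydrolase isozyme L3	S	161	No
Q15942	Zyxin	S	150	No
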