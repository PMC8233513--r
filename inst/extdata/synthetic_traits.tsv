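species	fpkm	body_mass_g	heart_rate_bpm	bmr
Mouse	41.2	20	600	1.17
Rat	35.8	300	350	0.68
Guinea_pig	12.4	700	270	0.51
Squirrel	9.6	500	300	0.55
Rabbit	22.1	2000	220	0.44
Pika	18.3	150	330	0.80
Human	0.4	70000	70	0.22
Chimpanzee	0.6	45000	90	0.24
Gorilla	0.3	120000	70	0.20
Rhesus_macaque	15.2	8000	160	0.30
Marmoset	11.0	350	230	0.58
Mouse_lemur	8.9	60	400	0.70
Cow	3.1	600000	60	0.14
Sheep	4.8	60000	90	0.22
Goat	5.2	50000	90	0.23
Pig	6.7	150000	90	0.20
Horse	1.9	450000	40	0.15
Dog	2.8	20000	100	0.28
Cat	3.5	4000	150	0.34
Ferret	14.6	1000	250	0.49
Panda	1.2	100000	80	0.18
Microbat	28.7	8	500	1.30
Megabat	7.4	800	250	0.45
Hedgehog	13.9	500	250	0.52
Shrew	44.0	5	700	1.60
Elephant	0.5	4500000	30	0.07
Hyrax	6.1	3000	180	0.31
Armadillo	2.2	4000	120	0.25
Opossum	10.5	2500	200	0.38
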