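aa	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	-0.4899999999999999	-0.5444444444444444	-0.0777777777777778	-0.0777777777777778	-0.5677777777777777	-0.3188888888888888	-0.10111111111111110	-0.7000000000000000	-0.04666666666666668	-0.6455555555555555	-0.4977777777777778	-0.07777777777777777	-0.2255555555555555	-0.07777777777777777	0.0	-0.2877777777777778	-0.2955555555555555	-0.6766666666666665	-0.2800000000000000	-0.2488888888888889
C	-0.5444444444444444	-0.6049382716049383	-0.0864197530864197	-0.0864197530864197	-0.6308641975308642	-0.3543209876543210	-0.11234567901234567	-0.7777777777777778	-0.05185185185185186	-0.7172839506172840	-0.5530864197530865	-0.08641975308641975	-0.2506172839506173	-0.08641975308641975	0.0	-0.3197530864197531	-0.3283950617283951	-0.7518518518518518	-0.3111111111111111	-0.2765432098765432
D	-0.0777777777777778	-0.0864197530864197	0.3876543209876543	0.3876543209876543	-0.0901234567901235	-0.0506172839506173	-0.01604938271604938	-0.1111111111111111	0.39259259259259260	-0.1024691358024691	-0.0790123456790123	-0.01234567901234568	-0.0358024691358025	-0.01234567901234568	0.4	-0.0456790123456790	-0.0469135802469136	-0.1074074074074074	-0.0444444444444444	-0.0395061728395062
E	-0.0777777777777778	-0.0864197530864197	0.3876543209876543	0.3876543209876543	-0.0901234567901235	-0.0506172839506173	-0.01604938271604938	-0.1111111111111111	0.39259259259259260	-0.1024691358024691	-0.0790123456790123	-0.01234567901234568	-0.0358024691358025	-0.01234567901234568	0.4	-0.0456790123456790	-0.0469135802469136	-0.1074074074074074	-0.0444444444444444	-0.0395061728395062
F	-0.5677777777777777	-0.6308641975308642	-0.0901234567901235	-0.0901234567901235	-0.6579012345679013	-0.3695061728395061	-0.11716049382716048	-0.8111111111111111	-0.05407407407407409	-0.7480246913580247	-0.5767901234567901	-0.09012345679012346	-0.2613580246913580	-0.09012345679012346	0.0	-0.3334567901234568	-0.3424691358024691	-0.7840740740740740	-0.3244444444444445	-0.2883950617283951
G	-0.3188888888888888	-0.3543209876543210	-0.0506172839506173	-0.0506172839506173	-0.3695061728395061	-0.2075308641975308	-0.06580246913580245	-0.4555555555555555	-0.03037037037037037	-0.4201234567901234	-0.3239506172839506	-0.05061728395061727	-0.1467901234567901	-0.05061728395061727	0.0	-0.1872839506172840	-0.1923456790123456	-0.4403703703703702	-0.1822222222222222	-0.1619753086419753
H	-0.1011111111111111	-0.1123456790123457	-0.0160493827160494	-0.0160493827160494	-0.1171604938271605	-0.0658024691358025	-0.02086419753086419	-0.1444444444444444	-0.00962962962962963	-0.1332098765432099	-0.1027160493827160	-0.01604938271604938	-0.0465432098765432	-0.01604938271604938	0.0	-0.0593827160493827	-0.0609876543209876	-0.1396296296296296	-0.0577777777777778	-0.0513580246913580
I	-0.7000000000000000	-0.7777777777777778	-0.1111111111111111	-0.1111111111111111	-0.8111111111111111	-0.4555555555555555	-0.14444444444444443	-1.0000000000000000	-0.06666666666666668	-0.9222222222222223	-0.7111111111111111	-0.11111111111111110	-0.3222222222222222	-0.11111111111111110	0.0	-0.4111111111111111	-0.4222222222222222	-0.9666666666666666	-0.4000000000000000	-0.3555555555555556
K	-0.0466666666666667	-0.0518518518518519	0.3925925925925926	0.3925925925925926	-0.0540740740740741	-0.0303703703703704	-0.00962962962962963	-0.0666666666666667	0.39555555555555555	-0.0614814814814815	-0.0474074074074074	-0.00740740740740741	-0.0214814814814815	-0.00740740740740741	0.4	-0.0274074074074074	-0.0281481481481482	-0.0644444444444445	-0.0266666666666667	-0.0237037037037037
L	-0.6455555555555555	-0.7172839506172840	-0.1024691358024691	-0.1024691358024691	-0.7480246913580247	-0.4201234567901234	-0.13320987654320987	-0.9222222222222223	-0.06148148148148150	-0.8504938271604939	-0.6558024691358025	-0.10246913580246914	-0.2971604938271605	-0.10246913580246914	0.0	-0.3791358024691359	-0.3893827160493827	-0.8914814814814814	-0.3688888888888889	-0.3279012345679013
M	-0.4977777777777778	-0.5530864197530865	-0.0790123456790123	-0.0790123456790123	-0.5767901234567901	-0.3239506172839506	-0.10271604938271604	-0.7111111111111111	-0.04740740740740742	-0.6558024691358025	-0.5056790123456790	-0.07901234567901234	-0.2291358024691358	-0.07901234567901234	0.0	-0.2923456790123457	-0.3002469135802469	-0.6874074074074074	-0.2844444444444444	-0.2528395061728395
N	-0.0777777777777778	-0.0864197530864197	-0.0123456790123457	-0.0123456790123457	-0.0901234567901235	-0.0506172839506173	-0.01604938271604938	-0.1111111111111111	-0.00740740740740741	-0.1024691358024691	-0.0790123456790123	-0.01234567901234568	-0.0358024691358025	-0.01234567901234568	0.0	-0.0456790123456790	-0.0469135802469136	-0.1074074074074074	-0.0444444444444444	-0.0395061728395062
P	-0.2255555555555555	-0.2506172839506173	-0.0358024691358025	-0.0358024691358025	-0.2613580246913580	-0.1467901234567901	-0.04654320987654320	-0.3222222222222222	-0.02148148148148148	-0.2971604938271605	-0.2291358024691358	-0.03580246913580246	-0.1038271604938271	-0.03580246913580246	0.0	-0.1324691358024691	-0.1360493827160494	-0.3114814814814814	-0.1288888888888889	-0.1145679012345679
Q	-0.0777777777777778	-0.0864197530864197	-0.0123456790123457	-0.0123456790123457	-0.0901234567901235	-0.0506172839506173	-0.01604938271604938	-0.1111111111111111	-0.00740740740740741	-0.1024691358024691	-0.0790123456790123	-0.01234567901234568	-0.0358024691358025	-0.01234567901234568	0.0	-0.0456790123456790	-0.0469135802469136	-0.1074074074074074	-0.0444444444444444	-0.0395061728395062
R	0.0000000000000000	0.0000000000000000	0.4000000000000000	0.4000000000000000	0.0000000000000000	0.0000000000000000	0.00000000000000000	0.0000000000000000	0.40000000000000002	0.0000000000000000	0.0000000000000000	0.00000000000000000	0.0000000000000000	0.00000000000000000	0.4	0.0000000000000000	0.0000000000000000	0.0000000000000000	0.0000000000000000	0.0000000000000000
S	-0.2877777777777778	-0.3197530864197531	-0.0456790123456790	-0.0456790123456790	-0.3334567901234568	-0.1872839506172840	-0.05938271604938272	-0.4111111111111111	-0.02740740740740742	-0.3791358024691359	-0.2923456790123457	-0.04567901234567901	-0.1324691358024691	-0.04567901234567901	0.0	-0.1690123456790124	-0.1735802469135803	-0.3974074074074074	-0.1644444444444445	-0.1461728395061729
T	-0.2955555555555555	-0.3283950617283951	-0.0469135802469136	-0.0469135802469136	-0.3424691358024691	-0.1923456790123456	-0.06098765432098765	-0.4222222222222222	-0.02814814814814815	-0.3893827160493827	-0.3002469135802469	-0.04691358024691358	-0.1360493827160494	-0.04691358024691358	0.0	-0.1735802469135803	-0.1782716049382716	-0.4081481481481481	-0.1688888888888889	-0.1501234567901235
V	-0.6766666666666665	-0.7518518518518518	-0.1074074074074074	-0.1074074074074074	-0.7840740740740740	-0.4403703703703702	-0.13962962962962960	-0.9666666666666666	-0.06444444444444446	-0.8914814814814814	-0.6874074074074074	-0.10740740740740740	-0.3114814814814814	-0.10740740740740740	0.0	-0.3974074074074074	-0.4081481481481481	-0.9344444444444442	-0.3866666666666667	-0.3437037037037037
W	-0.2800000000000000	-0.3111111111111111	-0.0444444444444444	-0.0444444444444444	-0.3244444444444445	-0.1822222222222222	-0.05777777777777778	-0.4000000000000000	-0.02666666666666667	-0.3688888888888889	-0.2844444444444444	-0.04444444444444445	-0.1288888888888889	-0.04444444444444445	0.0	-0.1644444444444445	-0.1688888888888889	-0.3866666666666667	-0.1600000000000000	-0.1422222222222222
Y	-0.2488888888888889	-0.2765432098765432	-0.0395061728395062	-0.0395061728395062	-0.2883950617283951	-0.1619753086419753	-0.05135802469135802	-0.3555555555555556	-0.02370370370370371	-0.3279012345679013	-0.2528395061728395	-0.03950617283950617	-0.1145679012345679	-0.03950617283950617	0.0	-0.1461728395061729	-0.1501234567901235	-0.3437037037037037	-0.1422222222222222	-0.1264197530864198
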