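index	name	states	n_states
1	Gill	0=present; 1=absent	2
2	Gill position	0=lateral; 1=dorsal	2
3	Body shape	0=oval; 1=wedge; 2=elongate	3
4	Rhinophoral ridge	0=present; 1=absent	2
5	Notal ridges	0=absent; 1=present	2
6	Notal tubercles	0=absent; 1=present	2
7	Notal cerata	0=absent; 1=present	2
8	Oral structures	0=none; 1=tentacles; 2=veil	3
9	Oral veil	0=no projections; 1=projections	2
10	Cephalic structure	0=absent; 1=present	2
11	Caruncle	0=absent; 1=present	2
12	Rhinophoral lamellae	0=horizontal; 1=vertical; 2=none	3
13	Anus position	0=above pallial margin; 1=below pallial margin	2
14	Foot tentacles	0=absent; 1=present	2
15	Anterior foot border	0=not notched; 1=notched	2
16	Branchial lamellae	0=absent; 1=present	2
17	Hyponotal lamellae	0=absent; 1=present	2
18	Radula shape	0=broader than long; 1=slightly longer than broad; 2=much longer than broad	3
19	Rachidian tooth	0=absent; 1=present	2
20	Rachidian tooth denticles	0=none; 1=denticulate	2
21	Rachidian tooth denticle number	0=few (<=5); 1=many (>5)	2
22	Rachidian central cusp	0=not projecting; 1=slightly projecting; 2=greatly projecting	3
23	Rachidian tooth shape	0=narrow; 1=broad	2
24	Top of rachidian tooth	0=flat or slightly indented; 1=elongate bases and deep notches	2
25	Inner lateral tooth	0=smooth; 1=denticulate	2
26	Inner lateral tooth width	0=narrow; 1=medium; 2=broad	3
27	Inner lateral tooth shape	0=directed downward; 1=laterally directed	2
28	Second lateral tooth	0=denticulate; 1=smooth	2
29	Middle lateral teeth	0=denticulate; 1=smooth	2
30	Outer lateral teeth	0=denticulate; 1=smooth	2
31	Jaw	0=present; 1=absent	2
32	Masticatory border	0=distinct; 1=indistinct	2
33	Masticatory margin	0=denticulate; 1=smooth	2
34	Jaw denticles	0=seven to ten rows; 1=three to six rows; 2=one to two rows	3
35	Denticle location	0=along entire margin; 1=basally; 2=near hinge	3
36	Denticle shape	0=acutely pointed; 1=rounded; 2=multifid	3
37	Reproductive system	0=androdiaulic; 1=diaulic; 2=triaulic	3
38	Ampulla	0=tubular; 1=mass	2
39	Penial sheath	0=bulbous; 1=narrow	2
40	Deferent duct	0=long; 1=short	2
41	Bursa duct	0=distinct duct present; 1=bursa duct absent	2
42	Vaginal duct	0=long; 1=short	2
43	Vaginal width	0=uniform; 1=basally wider	2
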