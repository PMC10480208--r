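module_id	definition
M_COB1	K0201 K0202 (K0203,K0204) K0205 K0206+K0207 K0208 K0209 K0210 K0211
M_MARKER	K00548 K01847 K03500
M_AA01	K0301 K0302 (K0303,K0304)
M_AA02	K0311 K0312+K0313 K0314
M_AA03	(K0321,K0322) K0323 K0324 K0325
M_VIT01	K0401 K0402 K0403
M_VIT02	K0411 (K0412,K0413) K0414 -K0415
M_VIT03	K0421 K0422
M_LIP01	K0501 K0502 K0503 K0504
M_LIP02	K0511+K0512 K0513
M_LIP03	((K0521 K0522),(K0523 K0524)) K0525
M_LIP04	K0531 K0532 (K0533,K0534+K0535)
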