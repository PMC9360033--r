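code	category	unbalanced	autosomal_monosomy	tp53_locus_loss
t(15;17)	fusion	FALSE	FALSE	FALSE
inv(16)	fusion	FALSE	FALSE	FALSE
t(8;21)	fusion	FALSE	FALSE	FALSE
t(9;11)	fusion	FALSE	FALSE	FALSE
t(11;x)	fusion	FALSE	FALSE	FALSE
t(6;9)	fusion	FALSE	FALSE	FALSE
inv(3)	fusion	FALSE	FALSE	FALSE
+8	gain	TRUE	FALSE	FALSE
+11	gain	TRUE	FALSE	FALSE
+13	gain	TRUE	FALSE	FALSE
+21	gain	TRUE	FALSE	FALSE
+22	gain	TRUE	FALSE	FALSE
-5	loss	TRUE	TRUE	FALSE
-7	loss	TRUE	TRUE	FALSE
-17	loss	TRUE	TRUE	TRUE
-X/-Y	loss	TRUE	FALSE	FALSE
del(5q)	deletion	TRUE	FALSE	FALSE
del(7q)	deletion	TRUE	FALSE	FALSE
del(9q)	deletion	TRUE	FALSE	FALSE
del(17p)	deletion	TRUE	FALSE	TRUE
other_unbalanced	other	TRUE	FALSE	FALSE
other_balanced	other	FALSE	FALSE	FALSE
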