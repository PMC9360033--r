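# Default 32-gene AML classification panel.
# The 11 sAML class-defining features (saml_class_defining = TRUE) are the
# secondary-AML-type genes SRSF2, SF3B1, U2AF1, ZRSR2, ASXL1, EZH2, BCOR,
# STAG2 plus RUNX1, SETBP1 and MLL-PTD (MLL counts only with a PTD-
# consequence call, flagged by ptd_only).
# Genes beyond the explicitly named class-defining set are a representative
# default of canonical recurrent AML drivers; replace via load_panel() to
# match a local assay.
gene	saml_class_defining	ptd_only
SRSF2	TRUE	FALSE
SF3B1	TRUE	FALSE
U2AF1	TRUE	FALSE
ZRSR2	TRUE	FALSE
ASXL1	TRUE	FALSE
EZH2	TRUE	FALSE
BCOR	TRUE	FALSE
STAG2	TRUE	FALSE
RUNX1	TRUE	FALSE
SETBP1	TRUE	FALSE
MLL	TRUE	TRUE
NPM1	FALSE	FALSE
CEBPA	FALSE	FALSE
WT1	FALSE	FALSE
DNMT3A	FALSE	FALSE
IDH1	FALSE	FALSE
IDH2	FALSE	FALSE
TP53	FALSE	FALSE
FLT3	FALSE	FALSE
NRAS	FALSE	FALSE
KRAS	FALSE	FALSE
KIT	FALSE	FALSE
TET2	FALSE	FALSE
PTPN11	FALSE	FALSE
GATA2	FALSE	FALSE
JAK2	FALSE	FALSE
CBL	FALSE	FALSE
CSF3R	FALSE	FALSE
PHF6	FALSE	FALSE
RAD21	FALSE	FALSE
U2AF2	FALSE	FALSE
DDX41	FALSE	FALSE
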