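!Series_title	"Synthetic miniature series for parser tests"
!Series_geo_accession	"GSE00000"
!Sample_title	"tumor sample 1"	"tumor sample 2"	"tumor sample 3"
!Sample_geo_accession	"GSM000001"	"GSM000002"	"GSM000003"
!Sample_characteristics_ch1	"histology: GBM"	"histology: GBM"	"histology: astrocytoma"
!Sample_characteristics_ch1	"survival_months: 12.5"	"survival_months: 3.1"	"survival_months: 40.2"
!series_matrix_table_begin
ID_REF	GSM000001	GSM000002	GSM000003
50848	8.91	9.44	7.02
968	6.15	6.88	6.40
199	5.02	4.97	5.10
1520	7.77	8.01	7.65
!series_matrix_table_end
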