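allele_id	Mu1	Mu2	Mu3	Mu4	Mu5	Mu6	Mu7	Mu8	Mu9	Mu10	Mu11	Mu12	Mu13	functionality
Aa-0	+	-	-	-	-	-	-	-	-	-	-	-	-	disabled
Ag-0	-	-	-	-	-	-	-	-	-	-	-	-	-	functional
Ba-1	-	-	-	-	-	-	-	-	-	-	-	-	+	disabled
Col-0	+	-	-	+	-	+	-	+	-	-	-	+	-	disabled
Col-4	+	-	-	+	-	+	-	+	-	-	-	+	-	disabled
Col-J	+	-	-	+	-	+	-	+	-	-	-	+	-	disabled
Cvi-0	+	-	-	+	-	+	-	+	-	-	-	+	-	disabled
Bsch-0	-	-	-	-	-	-	-	-	-	-	-	-	-	functional
Edi-0	-	-	-	-	-	-	-	-	-	-	-	-	+	disabled
Gel-0	-	-	-	-	-	-	-	-	-	-	-	-	-	functional
Gre-0	-	-	+	-	-	-	-	-	+	-	-	-	-	disabled
JM-1	-	-	-	+	-	-	-	-	-	-	-	-	-	disabled
JM-2	-	-	-	+	-	-	-	-	-	-	-	-	-	disabled
Kas-1	+	-	-	-	-	-	-	-	-	-	-	-	-	disabled
La-0	-	-	-	-	-	-	-	-	-	-	-	-	-	functional
Ler-1	-	-	-	-	-	-	-	-	-	-	-	-	-	functional
Mir-0	-	-	-	-	+	-	-	-	-	-	+	-	-	disabled
Mz-0	-	-	-	-	-	-	-	-	-	+	-	-	-	disabled
Mr-0	-	-	-	-	-	-	-	-	-	-	-	-	-	functional
Oy-0	-	-	-	-	-	-	-	-	-	-	-	-	-	functional
Pr-0	+	+	N/A	-	-	-	+	-	-	-	-	-	-	disabled
Stw-0	+	-	-	-	-	-	-	-	-	+	-	-	-	disabled
Ts-6	-	-	-	-	+	-	-	-	-	-	-	-	-	disabled
Tsu-0	-	-	-	-	-	-	-	-	-	-	-	-	-	functional
Tul-0	-	-	+	-	-	-	-	-	+	-	-	-	-	disabled
Ty-0	-	-	-	-	-	-	-	-	-	-	-	-	-	functional
Van	-	-	-	-	-	-	-	-	-	+	-	-	-	disabled
Ws-0	-	-	+	-	-	-	-	-	-	-	-	-	-	disabled
Wil-0	-	-	-	-	-	-	-	-	-	-	-	-	-	functional
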