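# Synthetic default list of recurrently mutated cancer-driver gene symbols
# for feature annotation. Replace with a catalogue-derived list for real
# analyses (driver status is study-specific).
TP53
BRAF
NRAS
KRAS
PTEN
CDKN2A
NF1
PIK3CA
EGFR
KIT
CTNNB1
IDH1
ARID2
PPP6C
RAC1
MAP2K1
STK19
RB1
SMARCA4
AKAP9
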