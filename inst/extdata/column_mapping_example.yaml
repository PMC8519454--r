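# Example column mapping for read_survey(): keys are the codebook names the
# package expects, values are the column names as they appear in an external
# survey file. Only columns that differ need an entry.
item01: viol_humiliate
item02: viol_threaten
item03: viol_insult
site: slum
agegrp: age_group
hungry: slept_hungry_4wk
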