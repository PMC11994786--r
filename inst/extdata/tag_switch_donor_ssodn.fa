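>tag_switch_donor_ssodn 292-nt single-strand oligo donor, loxP-3xHA-loxP-V5 switchable cassette
GGTCAGGAGTTGGGTCCTGTGCATTTGCCACAGTGGAAGACTACCTACATATAACTTCGT
ATAGCCTACATTATACGAAGTTATCTTACCCATACGATGTTCCAGATTACGCTTACCCAT
ACGATGTTCCAGATTACGCTTACCCATACGATGTTCCAGATTACGCTTAGCATAACTTCG
TATAGCCTACATTATACGAAGTTATCTGGTAAGCCTATCCCTAACCCTCTCCTCGGTCTC
GATTCTACGTAGCTATGCACTTCAAGAGCTCACACTCACATTGTGGCAAACA
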