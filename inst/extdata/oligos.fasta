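>adapter_5np1 LEAP 3' RACE adapter; single cytidine in a 5'-TCA-3' context
GATGGATGATGAATAAAGTGTGGGATGATCATGATGTATGGATAGGTTTTTTTTTTTT
>adapter_5np1_outer outer PCR primer
GATGGATGATGAATAAAGTG
>l1_3end L1 3' end PCR primer
GGGTTCGAAATCGATAAGCTTGGATCCAGAC
>fitc_tca FITC-labelled single-strand deaminase substrate; single C in 5'-TCA-3'
TATTATTATTATTATTATTCATTTATTTATTTATTTATTT
>neo_as_reco 5' recovery-cassette sequencing primer
TCTATCGCCTTCTTGACGAG
>rescue3seq 3' recovery-cassette sequencing primer
ACTCACGTTAAGGGATTTTGGTCA
>polyAseq oligo(dA) anchored sequencing primer (IUPAC B/N anchor)
AAAAAAAAAAAAAAAAAAAABN
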