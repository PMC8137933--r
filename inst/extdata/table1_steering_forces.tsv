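peptide	mean	sd	printed_score
YRGWHCRGITKNGIIFDIKW	621.3	6.0	628.0
DIGWDTEHPPKTCQIICSVI	648.6	26.5	678.2
KIGHQKIIGETQKRCFFQWV	639.1	36.7	680.1
LMQPVTKICTNGHCTGQFFG	681.5	9.7	692.3
RTCKRVHLGVLNVFNTCHYC	643.5	69.5	721.2
IGGVKAIMSRERPIKIKCTK	668.9	55.0	730.4
ELMLNGWISAGTCQRIWGSR	615.1	117.6	746.6
PCIKIFFCKSLFCRNVRETK	766.7	20.7	789.9
FRHCFPPQAQCTVEIGWVDI	699.2	89.4	799.1
FIWGKVAIRCFHNTFCKRHC	645.5	146.5	809.2
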