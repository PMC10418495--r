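file	md5	note
table_maximum_range.tsv	2e71c1f29bafe6875a84d009fe49e7d2	Maximum-range member counts [A-T counts] per energy x region x size group; '-' encoded as all_closed=TRUE
table_minimum_range.tsv	5f3ab43b11b39c9b4415d2ff7d74b469	Minimum-range member counts likewise
table_composition.tsv	dcef6d86a29e588690a431b172091c4f	three-region sizes and A-T/G-C percentages
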