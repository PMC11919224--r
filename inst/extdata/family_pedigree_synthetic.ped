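# Synthetic reconstruction of the three multicase-family pedigrees.
# Family 1 follows the published diagram (two ungenotyped parents, seven
# genotyped offspring); families 2 and 3 are plausible three-generation
# structures consistent with published member counts, affection statuses
# and the MZ twin pair 3-1/3-7. Sexes of most members are arbitrary.
# Columns: family_id individual_id father_id mother_id sex affection mz_group
1 1-1  0   0   1 1 0
1 1-2  0   0   2 1 0
1 1-3  1-1 1-2 2 2 0
1 1-4  1-1 1-2 1 2 0
1 1-5  1-1 1-2 2 2 0
1 1-7  1-1 1-2 1 1 0
1 1-8  1-1 1-2 2 1 0
1 1-9  1-1 1-2 1 1 0
1 1-10 1-1 1-2 2 1 0
2 2-1  0   0   2 2 0
2 2-7  0   0   1 0 0
2 2-2  2-7 2-1 2 2 0
2 2-4  2-7 2-1 1 1 0
2 2-8  0   0   1 0 0
2 2-3  2-8 2-2 2 2 0
2 2-5  2-8 2-2 1 1 0
2 2-6  2-8 2-2 2 2 0
3 3-8  0   0   1 0 0
3 3-9  0   0   2 0 0
3 3-1  3-8 3-9 1 2 mz1
3 3-7  3-8 3-9 1 0 mz1
3 3-2  3-8 3-9 2 2 0
3 3-3  3-8 3-9 2 1 0
3 3-4  3-8 3-9 1 1 0
3 3-10 0   0   2 0 0
3 3-5  3-1 3-10 1 1 0
3 3-6  3-1 3-10 2 1 0
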