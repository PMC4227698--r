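# Synthetic reconstruction of blocker structures for the complexity module.
# The PEG-based blockers (PQ0-PQ5) are rebuilt from their published
# structural description: an octa(ethylene glycol)-derived backbone (seven
# ether oxygens after displacement of both terminal groups) carrying one
# quaternary ammonium group at each end. PQ1 = N-methylpyrrolidinium and
# PQ5 = N-methyldipropylammonium termini are stated explicitly; PQ2, PQ3
# and PQ4 (N-methylpiperidinium, N-methylazepanium, triethylammonium) are
# plausible reconstructions consistent with the stated QA-size ordering.
# Comparator blockers use their standard published structures (tubocurarine
# regiochemistry of the methoxy/hydroxy substituents approximated).
# kd_uM: PQ0-PQ5 are the published single-channel estimates; comparator
# affinities are approximate literature values for open-channel block of
# the muscle-type AChR and are indicative only.
name	pq_class	kd_uM	smiles
PQ0	PEG-based	9	C[N+](C)(C)CCOCCOCCOCCOCCOCCOCCOCC[N+](C)(C)C
PQ1	PEG-based	3	C[N+]1(CCOCCOCCOCCOCCOCCOCCOCC[N+]2(C)CCCC2)CCCC1
PQ2	PEG-based	0.08	C[N+]1(CCOCCOCCOCCOCCOCCOCCOCC[N+]2(C)CCCCC2)CCCCC1
PQ3	PEG-based	0.17	C[N+]1(CCOCCOCCOCCOCCOCCOCCOCC[N+]2(C)CCCCCC2)CCCCCC1
PQ4	PEG-based	0.19	CC[N+](CC)(CC)CCOCCOCCOCCOCCOCCOCCOCC[N+](CC)(CC)CC
PQ5	PEG-based	0.12	CCC[N+](C)(CCC)CCOCCOCCOCCOCCOCCOCCOCC[N+](C)(CCC)CCC
tubocurarine	non-PEG-based	0.2	C[N+]1(C)CCc2cc(OC)c(Oc3cc(OC)c(CC4N(C)CCc5cc(O)c(O%13)cc45)cc3)cc2C1Cc6ccc%13c(O)c6
MK-801	non-PEG-based	0.4	CC12C3=CC=CC=C3CC(N1)C4=CC=CC=C24
physostigmine	non-PEG-based	20	CNC(=O)Oc1ccc2c(c1)C1(C)CCN(C)C1N2C
lamotrigine	non-PEG-based	200	Nc1nnc(-c2cccc(Cl)c2Cl)c(N)n1
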