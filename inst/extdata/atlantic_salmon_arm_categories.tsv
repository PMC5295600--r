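ssa_arm	charr_lg	category
Ssa01p	AC09
Ssa01qa	AC18q
Ssa01qb	AC29	AHP
Ssa02p	AC35	HRTA
Ssa02q	AC01q	HRTA
Ssa03p	AC19	AHP
Ssa03q	AC20b-1/AC20b-2	HRTA
Ssa04p	AC13q/AC-34	HRTA
Ssa04q	AC23
Ssa05p	AC06q
Ssa05q	AC06p	HRTA
Ssa06p	AC20a	HRTA
Ssa06q	AC14q
Ssa07p	AC03p
Ssa07q	AC03q	HRTA
Ssa08q	AC13q/AC34	HRTA
Ssa09qa	AC04qa
Ssa09qb	AC08p/AC08q
Ssa09qc	AC04p
Ssa10qa	AC16
Ssa10qb	AC04qb
Ssa11qa	AC10	HRTA
Ssa11qb	AC05	AHP
Ssa12qa	AC21	HRTA
Ssa12qb	AC01p
Ssa13qa	AC17qa
Ssa13qb	AC20b-2
Ssa14qa	AC32	AHP
Ssa14qb	AC30	AHP
Ssa15qa	AC28
Ssa15qb	AC07
Ssa16qa	AC26
Ssa16qb	AC27p	HRTA
Ssa17qa	AC12	HRTA
Ssa17qb	AC24	HRTA
Ssa18qa	AC25
Ssa18qb	AC37
Ssa19qa	AC17qb/AC14p
Ssa19qb	AC18p
Ssa20qa	AC14p/AC33
Ssa20qb	AC22
Ssa21	AC36	AHP
Ssa22	AC11
Ssa23	AC13p
Ssa24	AC15p
Ssa25	AC02	AHP
Ssa26	AC15q	HRTA
Ssa27	AC31	AHP
Ssa28	AC08p/AC08q
Ssa29	AC27q
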