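homeolog_1	homeolog_2
AC01p	AC11
AC01q	AC21
AC02	AC36
AC03p	AC24
AC03q	AC37
AC04p	AC14p/AC33
AC04p	AC22
AC04qa	AC09
AC04qb	AC26
AC06	AC08p/AC08q
AC06p	AC35
AC07	AC17qa
AC08p	AC18p
AC10	AC15q
AC12	AC27p
AC13p	AC16
AC13q	AC34
AC14q	AC28
AC15p	AC14p/AC14q/AC33
AC17qb	AC27q
AC18p	AC27q
AC18q	AC25
AC19	AC32
AC20b-1	AC20a
AC23	AC04qb/AC05/AC20b-1/AC-20b-2
AC29	AC05/AC20b-2
AC30	AC31
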