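>miR166a-3p
UCGGACCAGGCUUCAUUCCCC
>miR156a-5p
UGACAGAAGAGAGUGAGCAC
>miR159a
UUUGGAUUGAAGGGAGCUCUA
>miR167a-5p
UGAAGCUGCCAGCAUGAUCUA
>miR173-5p
UUCGCUUGCAGAGAGAAAUCAC
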