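>synthetic_sticker_rich synthetic test peptide, not a natural sequence
GRGYSGQNFGSRGQYGGSGFGQNRGYSG
>synthetic_charged synthetic test peptide with charge patches
GDEDEDGSKRKRKGSDEDEDGSKRKRKG
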