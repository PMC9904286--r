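dialect,role,pattern
generic,delim,comma
generic,sequence,peptide
generic,replicate,sample
generic,psm,psm
generic,intensity,intensity
generic,area,area
generic,ptm,ptm
peaks,delim,comma
peaks,sequence,Peptide
peaks,psm,^#Spec (.+)$
peaks,intensity,^Intensity (.+)$
peaks,area,^Area (.+)$
msfragger,delim,tab
msfragger,sequence,Peptide Sequence
msfragger,psm,^(.+) Spectral Count$
msfragger,area,^(.+) Intensity$
maxquant,delim,tab
maxquant,sequence,Sequence
maxquant,psm,^MS/MS Count (.+)$
maxquant,area,^Intensity (.+)$
metamorpheus,delim,tab
metamorpheus,sequence,Full Sequence
metamorpheus,psm,^PSM Count_(.+)$
metamorpheus,area,^Intensity_(.+)$
proteome_discoverer,delim,comma
proteome_discoverer,sequence,Annotated Sequence
proteome_discoverer,psm,^# PSMs (.+)$
proteome_discoverer,area,^Abundance (.+)$
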