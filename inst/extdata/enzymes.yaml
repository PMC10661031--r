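# Restriction enzyme geometries (REBASE conventions).
# For Type IIS enzymes, cut_top/cut_bottom are offsets measured from the 3'
# end of the recognition site on the recognition strand: BsaI = GGTCTC(1/5).
# For within-site cutters (type_iis: false), the offsets are measured from
# the 5' start of the recognition site: NotI = GC^GGCCGC.
enzymes:
- name: BsaI
  recognition: GGTCTC
  cut_top: 1
  cut_bottom: 5
  type_iis: true
- name: BsmBI
  recognition: CGTCTC
  cut_top: 1
  cut_bottom: 5
  type_iis: true
- name: BbsI
  recognition: GAAGAC
  cut_top: 2
  cut_bottom: 6
  type_iis: true
- name: NotI
  recognition: GCGGCCGC
  cut_top: 2
  cut_bottom: 6
  type_iis: false
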