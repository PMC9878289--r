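# Default SMN locus model (hg38, SMN1-anchored coordinates, 1-based inclusive).
#
# The three PSV positions are the published SMN1 exon 7 discriminating sites.
# Only the base pair at chr5:70247773 (canonical c.840C>T) is a documented
# SMN1/SMN2 difference; the base pairs at 70247724 and 70247921 are
# PLACEHOLDERS -- edit them to the panel's validated PSV alleles.
# Control-gene intervals are synthetic stand-ins for a capture panel's
# diploid normalisation targets; replace with real panel intervals.
psv_sites:
  - {chrom: chr5, pos: 70247724, smn1_base: A, smn2_base: G}
  - {chrom: chr5, pos: 70247773, smn1_base: C, smn2_base: T}
  - {chrom: chr5, pos: 70247921, smn1_base: G, smn2_base: A}
exon7:
  {chrom: chr5, start: 70247700, end: 70247940, label: SMN1_exon7_target}
smn_region:
  {chrom: chr5, start: 70247420, end: 70248260, label: SMN1_exon7_capture}
control_genes:
  - {chrom: chr1, start: 11000001, end: 11001000, label: CTRL_A}
  - {chrom: chr2, start: 24000001, end: 24001000, label: CTRL_B}
  - {chrom: chr17, start: 5000001, end: 5001000, label: CTRL_C}
thresholds:
  min_control_depth: 20        # X; sample fails if mean control depth < 20
  min_uniformity: 0.95         # fraction of control bases >= 0.2 x mean depth
  min_base_quality: 20         # Phred gate on PSV base observations
  deletion_score_cutoff: 0.5   # copy-equivalents; score below => POSITIVE
  min_psv_total_depth: 20      # mean reads across PSV sites; below => FAIL
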