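# Annotated germsoma run configuration. Any field omitted falls back to
# the package default (see germsoma::load_config()).

seed: 1                    # global seed; fanned out to per-stage sub-seeds
out_dir: germsoma_demo     # all stage outputs land under this directory

stages:                    # every stage can be toggled independently
  simulate: true           # generate all inputs synthetically
  assoc: true              # gene x signature scan + permutation null
  loci: true               # 1 Mb risk-locus construction
  hotspots: true           # element burden test + enrichment
  cna: true                # recurrent CNA calling + state coverage
  tfbs: true               # germline/somatic TFBS disruption
  report: true             # human-readable digest

simulate:
  n_chroms: 2
  chrom_size: 3000000      # bp per chromosome
  n_samples_expr: 89       # expression / signature-activity cohort
  n_genes: 300
  n_signatures: 12
  n_planted_assoc: 3       # planted gene-signature couplings
  n_samples_snv: 40        # somatic SNV cohort
  background_rate: 2.0e-5  # mutations / bp / sample
  n_hotspots: 3
  hotspot_multiplier: 30   # fold-increase over background inside hotspots
  n_samples_cna: 40
  n_cna_regions: 2
  cna_penetrance: 0.7
  n_tfs: 4
  motif_len: 8
  n_loci: 4

assoc:
  alpha: 0.05              # nominal per-pair significance threshold
  n_permutations: 1000
  log2_expr: true          # log2(x+1)-transform expression before OLS

hotspots:
  fdr: 0.05                # BH q threshold per annotation track

cna:
  t_amp: 0.3               # seg.mean threshold for amplification
  t_del: -0.3
  bin_bp: 10000
  n_perm: 200              # circular permutations
  fdr: 0.25

tfbs:
  strong_site_threshold: 0.85
  delta_threshold: 0.10
  site_threshold: 0.85     # predicted-binding-site score floor
  min_mutations: 3         # per-element somatic burden filter

# To run on real data instead, disable simulate and point `inputs` at
# your files (TSV matrices, SNV TSV/VCF, SEG, BED tracks, JASPAR PFMs,
# FASTA, locus-index TSV):
#
# stages: {simulate: false}
# inputs:
#   expression: expr.tsv
#   activity: sigs.tsv
#   gene_list: genes.txt
#   snvs: snvs.tsv
#   snv_format: tsv
#   seg: segments.seg
#   loci_index: loci.tsv
#   tracks: [enhancer.bed, promoter.bed]
#   pwms: pwms.jaspar
#   fasta: genome.fa
#   credible_variants: credible.tsv
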