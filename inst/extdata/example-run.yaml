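# Example divaxes run configuration: fully synthetic data on all three axes.
# Replace the synthetic blocks with an inputs: block to analyze real files:
#   inputs:
#     climate_csv: climate.csv
#     morphology_csv: morphology.csv
#     loci: [mt_atp.fasta, gapdh.fasta]
#     sample_sheet: samples.tsv
seed: 1
fast: true
n_axes: 3
tail: two.sided
plus_one: false
ss_type: II
kst_weighting: size
deletion: complete
synthetic:
  climate:
    nPerGroup: [28, 8]
    nLatent: 3
    shift: [2.0, 0.0, 0.0]
    noiseSd: 1.0
  morphology:
    nPerSite: 7
  loci:
    nIndividuals: [12, 10]
    splitTime: 3.0
    loci:
      name: [mt_atp, gapdh, fib5, brm]
      genome: [mtDNA, autosomal, autosomal, Z]
      theta: [4.0, 2.0, 2.0, 2.0]
      locusLength: [800, 330, 520, 300]
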