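# Ten-replicate livestock genomic-selection scenario.
# 30 chromosomes, each 100 cM over ~1e8 bp; per-site mutation rate 2.5e-8;
# Holstein-like decline of effective population size; 4000 base haplotypes;
# 10-generation pedigree with 50 sires x 10 dams x 2 offspring; 60k and
# 300k SNP chips; 9000 candidate QTL (restricted set capped at MAF 0.30);
# gamma(0.4, 1.66) effects on a 900-locus subset; heritability 0.25.

[genome]
n_chromosomes = 30
genetic_length_cm = 100
physical_length_bp = 100000000
mutation_rate = 2.5e-08

[demography]
anchor = 0 100
anchor = 1000 1256
anchor = 10000 4350
anchor = 100000 43500
generation_interval = 1

[haplotypes]
source = coalescent
n_haplotypes = 4000

[pedigree]
source = internal
n_generations = 10
n_sires = 50
dams_per_sire = 10
offspring_per_dam = 2

[gene_drop]
crossover_rate_per_cm = 0.01

[chips]
chip = Chip60k 60000
chip = Chip300k 300000
nested = no

[qtl]
n_candidates = 9000
maf_threshold = 0.30

[traits]
heritability = 0.25
gamma_shape = 0.4
gamma_scale = 1.66
gamma_subset = 900

# Generations are labelled 0-based with the base generation as 0, so the
# scenario's 1-based "generations 4 and 5" (training) and "6, 8 and 10"
# (validation) are 3 4 and 5 7 9 here.
[split]
training_generations = 3 4
validation_generations = 5 7 9
validation_size = 500

[output]
seed = 1
sequence = no
phased = no
vcf = no
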