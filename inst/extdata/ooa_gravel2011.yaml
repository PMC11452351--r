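# Three-population human out-of-Africa demographic model.
# Parameter values from Gravel et al. (2011, PNAS 108:11983), the model
# fitted to 1000 Genomes low-coverage plus exome data; times converted
# to generations with 25 y/generation.  Populations: AFR (YRI-like),
# EUR (CEU-like), ASN (CHB-like); B is the out-of-Africa bottleneck
# population, A the ancestral population.
version: 1
N_A: 7310        # ancestral effective size
T_AF: 5920       # generations ago: AFR expansion (148 kya)
N_AF: 14474
T_B: 2040        # generations ago: out-of-Africa split (51 kya)
N_B: 1861
m_AF_B: 15.0e-5  # symmetric migration AFR <-> B
T_EU_AS: 920     # generations ago: EUR/ASN split (23 kya)
N_EU0: 1032      # EUR size at the split
r_EU: 0.0038     # EUR exponential growth per generation
N_AS0: 554       # ASN size at the split
r_AS: 0.0048     # ASN exponential growth per generation
m_AF_EU: 2.5e-5
m_AF_AS: 0.78e-5
m_EU_AS: 3.11e-5
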