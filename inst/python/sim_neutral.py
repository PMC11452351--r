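#!/usr/bin/env python
"""Neutral coalescent backend: msprime -> ms-format text.

Usage: sim_neutral.py <config.json> <out.ms>

Config keys:
  model: equilibrium | growth | bottleneck | ooa
  Ne, n_hap, length, mu, rec, reps, seed, Q (rescaling factor)
  growth:     ne_anc, ne_now, duration (generations)
  bottleneck: frac, start, duration (generations ago / generations)
  ooa:        parameter dict (see demography config shipped with the R
              package) plus sample_pop in {AFR, EUR, ASN}

Rescaling by Q divides population sizes and times by Q and multiplies
growth rates, migration rates, mu and rec by Q, leaving theta and rho
unchanged.  Mutations use a binary 0/1 model on a continuous genome
(infinite sites), so the ancestral state is 0 at every site.
"""
import json
import sys

import msprime


def build_demography(cfg, Q):
    # Config sizes are diploid Ne.  Sampling is haploid (ploidy=1), whose
    # pairwise coalescence rate is 1/(number of genomes), so every size
    # enters msprime as 2*Ne (then rescaled by Q).  Times divide by Q;
    # per-generation rates multiply by Q.
    model = cfg["model"]
    dem = msprime.Demography()

    def sz(ne):
        return 2.0 * ne / Q

    if model == "equilibrium":
        dem.add_population(name="pop0", initial_size=sz(cfg["Ne"]))
    elif model == "growth":
        dur = cfg["duration"] / Q
        import math
        rate = math.log(cfg["ne_now"] / cfg["ne_anc"]) / dur
        dem.add_population(name="pop0", initial_size=sz(cfg["ne_now"]),
                           growth_rate=rate)
        dem.add_population_parameters_change(
            time=dur, population="pop0", initial_size=sz(cfg["ne_anc"]),
            growth_rate=0)
    elif model == "bottleneck":
        start = cfg["start"] / Q       # older edge of the bottleneck
        dur = cfg["duration"] / Q
        dem.add_population(name="pop0", initial_size=sz(cfg["Ne"]))
        dem.add_population_parameters_change(
            time=max(start - dur, 0), population="pop0",
            initial_size=sz(cfg["Ne"] * cfg["frac"]))
        dem.add_population_parameters_change(
            time=start, population="pop0", initial_size=sz(cfg["Ne"]))
    elif model == "ooa":
        p = cfg["ooa"]
        import math
        t_eu_as = p["T_EU_AS"] / Q
        n_eu_now = p["N_EU0"] * math.exp(p["r_EU"] * p["T_EU_AS"])
        n_as_now = p["N_AS0"] * math.exp(p["r_AS"] * p["T_EU_AS"])
        dem.add_population(name="AFR", initial_size=sz(p["N_AF"]))
        dem.add_population(name="EUR", initial_size=sz(n_eu_now),
                           growth_rate=p["r_EU"] * Q)
        dem.add_population(name="ASN", initial_size=sz(n_as_now),
                           growth_rate=p["r_AS"] * Q)
        dem.add_population(name="B", initial_size=sz(p["N_B"]))
        dem.add_population(name="AMH", initial_size=sz(p["N_AF"]))
        dem.add_population(name="ANC", initial_size=sz(p["N_A"]))
        dem.set_symmetric_migration_rate(["AFR", "EUR"], p["m_AF_EU"] * Q)
        dem.set_symmetric_migration_rate(["AFR", "ASN"], p["m_AF_AS"] * Q)
        dem.set_symmetric_migration_rate(["EUR", "ASN"], p["m_EU_AS"] * Q)
        dem.add_population_split(time=t_eu_as, derived=["EUR", "ASN"],
                                 ancestral="B")
        dem.add_symmetric_migration_rate_change(
            time=t_eu_as, populations=["AFR", "B"], rate=p["m_AF_B"] * Q)
        dem.add_population_split(time=p["T_B"] / Q, derived=["AFR", "B"],
                                 ancestral="AMH")
        dem.add_population_split(time=p["T_AF"] / Q, derived=["AMH"],
                                 ancestral="ANC")
    else:
        raise ValueError("unknown model: %s" % model)
    return dem


def main():
    with open(sys.argv[1]) as fh:
        cfg = json.load(fh)
    Q = float(cfg.get("Q", 1.0))
    n_hap = int(cfg["n_hap"])
    length = float(cfg["length"])
    mu = float(cfg["mu"]) * Q
    rec = float(cfg["rec"]) * Q
    reps = int(cfg.get("reps", 1))
    seed = int(cfg["seed"])

    dem = build_demography(cfg, Q)
    if cfg["model"] == "ooa":
        samples = {cfg["ooa"].get("sample_pop", "AFR"): n_hap}
    else:
        samples = {"pop0": n_hap}

    anc = msprime.sim_ancestry(
        samples=samples, ploidy=1, demography=dem,
        sequence_length=length, recombination_rate=rec,
        num_replicates=reps, random_seed=seed)

    import numpy as np
    with open(sys.argv[2], "w") as out:
        out.write("ms %d %d\n%d\n" % (n_hap, reps, seed))
        for i, ts in enumerate(anc):
            mts = msprime.sim_mutations(
                ts, rate=mu, random_seed=seed + 1 + i,
                model=msprime.BinaryMutationModel(), discrete_genome=False)
            out.write("\n//\n")
            S = mts.num_sites
            out.write("segsites: %d\n" % S)
            if S:
                pos = mts.tables.sites.position / length
                out.write("positions: " +
                          " ".join("%.10f" % p for p in pos) + "\n")
                geno = mts.genotype_matrix()        # sites x haplotypes
                np.minimum(geno, 1, out=geno)
                txt = (geno.T.astype(np.uint8) + 48).tobytes()
                for j in range(n_hap):
                    out.write(txt[j * S:(j + 1) * S].decode("ascii"))
                    out.write("\n")
            else:
                out.write("positions:\n")


if __name__ == "__main__":
    main()
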