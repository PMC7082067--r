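"""Simulate multihetsep files for a scenario description.

Usage: python sim_scenario.py SCENARIO_FILE OUT_DIR SEED

Reads the plain key-value scenario format (deme / size / event / sample /
mu / rho / length / chromosomes), simulates each chromosome with msprime
(coalescent with recombination, finite-sites binary mutations) and writes
one multihetsep file per chromosome (chrom pos called alleles). Output is
fully determined by (scenario, seed). Prints the written paths.
"""

import os
import sys

import msprime


def read_scenario(path):
    demes, events, samples = {}, [], {}
    par = {"mu": 1.25e-8, "rho": 1e-8, "length": 1e8, "chromosomes": 22}
    with open(path) as fh:
        for line in fh:
            f = line.split()
            if not f or f[0].startswith("#"):
                continue
            key = f[0]
            if key == "deme":
                demes.setdefault(f[1], [])
            elif key == "size":
                demes.setdefault(f[1], []).append((float(f[2]), float(f[3])))
            elif key == "event":
                kind = f[1]
                if kind == "split":
                    events.append(("split", float(f[2]), f[3], f[4]))
                elif kind == "pulse":
                    events.append(("pulse", float(f[2]), f[3], f[4],
                                   float(f[5])))
                elif kind == "migration":
                    events.append(("migration", float(f[2]), float(f[3]),
                                   f[4], f[5], float(f[6])))
                else:
                    raise ValueError("unknown event kind " + kind)
            elif key == "sample":
                samples[f[1]] = int(f[2])
            elif key in par:
                par[key] = float(f[1])
            else:
                raise ValueError("unknown declaration " + key)
    par["chromosomes"] = int(par["chromosomes"])
    return demes, events, samples, par


def build_demography(demes, events):
    dem = msprime.Demography()
    for name, epochs in demes.items():
        epochs = sorted(epochs)
        dem.add_population(name=name, initial_size=epochs[0][1])
        for start, size in epochs[1:]:
            dem.add_population_parameters_change(
                time=start, initial_size=size, population=name)
    for ev in events:
        if ev[0] == "split":
            dem.add_mass_migration(time=ev[1], source=ev[2], dest=ev[3],
                                   proportion=1.0)
        elif ev[0] == "pulse":
            dem.add_mass_migration(time=ev[1], source=ev[2], dest=ev[3],
                                   proportion=ev[4])
        elif ev[0] == "migration":
            dem.add_symmetric_migration_rate_change(
                time=ev[1], populations=[ev[3], ev[4]], rate=ev[5])
            dem.add_symmetric_migration_rate_change(
                time=ev[2], populations=[ev[3], ev[4]], rate=0.0)
    dem.sort_events()
    return dem


def write_multihetsep(ts, chrom, path):
    n = ts.num_samples
    with open(path, "w") as out:
        prev = 0
        for var in ts.variants():
            if len(var.alleles) != 2:
                continue
            g = var.genotypes
            if g.min() == g.max():
                continue
            pos = int(var.site.position) + 1
            if pos <= prev:
                continue
            alleles = "".join("C" if g[i] else "A" for i in range(n))
            out.write("%s\t%d\t%d\t%s\n" % (chrom, pos, pos - prev, alleles))
            prev = pos


def main():
    scen_path, out_dir, seed = sys.argv[1], sys.argv[2], int(sys.argv[3])
    demes, events, samples, par = read_scenario(scen_path)
    dem = build_demography(demes, events)
    os.makedirs(out_dir, exist_ok=True)
    paths = []
    for name, n_hap in samples.items():
        if n_hap % 2:
            raise ValueError("haplotype counts must be even (diploid samples)")
    individuals = {name: n_hap // 2 for name, n_hap in samples.items()}
    for chrom in range(1, par["chromosomes"] + 1):
        ts = msprime.sim_ancestry(
            samples=individuals, demography=dem, ploidy=2,
            sequence_length=par["length"],
            recombination_rate=par["rho"],
            random_seed=seed + chrom)
        ts = msprime.sim_mutations(
            ts, rate=par["mu"], random_seed=seed + 100000 + chrom,
            model=msprime.BinaryMutationModel())
        path = os.path.join(out_dir, "chr%d.multihetsep.txt" % chrom)
        write_multihetsep(ts, str(chrom), path)
        paths.append(path)
    print("\n".join(paths))


if __name__ == "__main__":
    main()
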