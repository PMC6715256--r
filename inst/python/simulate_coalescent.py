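"""Coalescent simulation backend for the mshtc R package.

Simulates a sample of phased chromosomes with msprime, records per-variant-copy
truth (first coalescent time t_c, sister-branch length phi, and for singletons
under no recombination the distance x_AS to the nearest mutation on the focal
or sister branch) from the tree sequence, and writes plain-text outputs that
the R side parses:

  <out>/sim.vcf    phased diploid VCF (one ALT, GT with '|')
  <out>/truth.tsv  one row per retained variant copy
  <out>/trees.nwk  (optional) per-site newick marginal trees for cross-checks

Usage: python simulate_coalescent.py <config.json> <outdir>

Config keys: demography ("constant"|"growth"|"ooa"), n (sampled chromosomes,
even), L (bp), mu, rho, seed, N0 (constant size, default 1e4),
write_trees (bool), max_tree_sites (cap on exported newicks).

Sites retained: exactly one mutation (infinite-sites-like; recurrent or
back-mutated sites are dropped so ancestral/derived is unambiguous) and
derived count in [1, n-1]. x_AS is computed over retained sites only, so it
is on the same footing as msh values measured from the emitted VCF.
"""

import json
import math
import sys

import msprime


def build_demography(cfg):
    kind = cfg.get("demography", "constant")
    n0 = float(cfg.get("N0", 1e4))
    dem = msprime.Demography()
    if kind == "constant":
        dem.add_population(name="pop0", initial_size=n0)
        return dem, "pop0"
    if kind == "growth":
        # Exponential growth from Na=1e4 to N=5e5 over the last 200 generations.
        n_anc = float(cfg.get("Na", 1e4))
        n_now = float(cfg.get("Nfinal", 5e5))
        t_growth = float(cfg.get("T_growth", 200.0))
        rate = math.log(n_now / n_anc) / t_growth
        dem.add_population(name="pop0", initial_size=n_now, growth_rate=rate)
        dem.add_population_parameters_change(
            time=t_growth, population="pop0", initial_size=n_anc, growth_rate=0.0
        )
        return dem, "pop0"
    if kind == "ooa":
        # Three-population out-of-Africa model (Gutenkunst et al. 2009 point
        # estimates, generation time 25 y); sampling from the European deme.
        gen = 25.0
        N_A, N_AF, N_B = 7300.0, 12300.0, 2100.0
        N_EU0, r_EU = 1000.0, 0.004
        N_AS0, r_AS = 510.0, 0.0055
        T_AF = 220e3 / gen
        T_B = 140e3 / gen
        T_EU_AS = 21.2e3 / gen
        m_AF_B, m_AF_EU, m_AF_AS, m_EU_AS = 25e-5, 3e-5, 1.9e-5, 9.6e-5
        dem = msprime.Demography()
        dem.add_population(name="AF", initial_size=N_AF)
        dem.add_population(
            name="EU",
            initial_size=N_EU0 * math.exp(r_EU * T_EU_AS),
            growth_rate=r_EU,
        )
        dem.add_population(
            name="AS",
            initial_size=N_AS0 * math.exp(r_AS * T_EU_AS),
            growth_rate=r_AS,
        )
        dem.add_population(name="B", initial_size=N_B)
        dem.add_population(name="AMH", initial_size=N_AF)
        dem.add_population(name="ANC", initial_size=N_A)
        dem.set_symmetric_migration_rate(["AF", "EU"], m_AF_EU)
        dem.set_symmetric_migration_rate(["AF", "AS"], m_AF_AS)
        dem.set_symmetric_migration_rate(["EU", "AS"], m_EU_AS)
        dem.add_population_split(time=T_EU_AS, derived=["EU", "AS"], ancestral="B")
        dem.add_symmetric_migration_rate_change(
            time=T_EU_AS, populations=["AF", "B"], rate=m_AF_B
        )
        dem.add_population_split(time=T_B, derived=["AF", "B"], ancestral="AMH")
        dem.add_population_split(time=T_AF, derived=["AMH"], ancestral="ANC")
        dem.sort_events()
        return dem, "EU"
    raise ValueError("unknown demography: %s" % kind)


def retained_sites(ts, n):
    keep = []
    for site in ts.sites():
        if len(site.mutations) != 1:
            continue
        keep.append(site)
    return keep


def copy_truth(tree, focal, carriers_set, carrier_count):
    """First coalescence of the focal leaf's lineage with a non-carrier, and
    the sister branch length at that node."""
    u = focal
    p = tree.parent(u)
    while p != -1 and tree.num_samples(p) == carrier_count.get(p, 0):
        u = p
        p = tree.parent(u)
    if p == -1:  # cannot happen while a non-carrier exists
        raise RuntimeError("walked past the root")
    tc = tree.time(p)
    sisters = [c for c in tree.children(p) if c != u]
    # binary trees in practice; with a multifurcation take the oldest sister edge
    phi = max(tc - tree.time(c) for c in sisters)
    return tc, phi, p, sisters


def nearest_mut(site_pos, nodes, muts_by_node, L):
    """Per-direction distance from the focal base to the nearest retained-site
    mutation on the given branches; censored at the window bounds.
    Returns (d5, cens5, d3, cens3)."""
    left, right = None, None
    for node in nodes:
        for pos in muts_by_node.get(node, ()):  # retained sites only
            if pos < site_pos:
                d = site_pos - pos
                if left is None or d < left:
                    left = d
            elif pos > site_pos:
                d = pos - site_pos
                if right is None or d < right:
                    right = d
    cens5 = left is None
    cens3 = right is None
    if cens5:
        left = site_pos
    if cens3:
        right = L - site_pos
    return left, cens5, right, cens3


def write_vcf(path, chrom, positions, geno, n):
    assert n % 2 == 0
    with open(path, "w") as fh:
        fh.write("##fileformat=VCFv4.2\n")
        fh.write('##contig=<ID=%s>\n' % chrom)
        fh.write('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">\n')
        ids = ["tsk_%d" % i for i in range(n // 2)]
        fh.write(
            "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t"
            + "\t".join(ids)
            + "\n"
        )
        for pos, row in zip(positions, geno):
            gts = "\t".join(
                "%d|%d" % (row[2 * i], row[2 * i + 1]) for i in range(n // 2)
            )
            fh.write("%s\t%d\t.\tA\tT\t.\tPASS\t.\tGT\t%s\n" % (chrom, pos, gts))


def main(cfg_path, outdir):
    with open(cfg_path) as fh:
        cfg = json.load(fh)
    n = int(cfg["n"])
    if n % 2 != 0:
        raise ValueError("n must be even (diploid VCF output)")
    L = float(cfg["L"])
    mu = float(cfg["mu"])
    rho = float(cfg["rho"])
    seed = int(cfg["seed"])
    dem, sample_pop = build_demography(cfg)
    ts = msprime.sim_ancestry(
        samples={sample_pop: n // 2},
        demography=dem,
        sequence_length=L,
        recombination_rate=rho,
        random_seed=seed,
        ploidy=2,
    )
    ts = msprime.sim_mutations(
        ts,
        rate=mu,
        random_seed=seed + 1,
        model=msprime.BinaryMutationModel(),
        discrete_genome=True,
    )

    sites = retained_sites(ts, n)
    geno = ts.genotype_matrix()  # sites x samples
    chrom = str(cfg.get("chrom", "1"))

    # positions are 1-based in the VCF; msprime discrete positions start at 0
    keep_rows = []
    positions = []
    seen = set()
    for site in sites:
        pos1 = int(site.position) + 1
        if pos1 in seen:
            continue
        row = geno[site.id]
        k = int(row.sum())
        if k < 1 or k > n - 1:
            continue
        seen.add(pos1)
        keep_rows.append(site)
        positions.append(pos1)

    write_vcf(
        outdir + "/sim.vcf", chrom, positions, [geno[s.id] for s in keep_rows], n
    )

    # mutation positions (retained sites) per node, for x_AS
    want_xas = rho == 0.0 and bool(cfg.get("xas", True))
    muts_by_node = {}
    if want_xas:
        for site, pos1 in zip(keep_rows, positions):
            node = site.mutations[0].node
            muts_by_node.setdefault(node, []).append(pos1)

    write_trees = bool(cfg.get("write_trees", False))
    max_tree_sites = int(cfg.get("max_tree_sites", 200))
    tree_fh = open(outdir + "/trees.nwk", "w") if write_trees else None

    with open(outdir + "/truth.tsv", "w") as fh:
        fh.write("pos\trow\tk\ttc\tphi\txas5\tcens5\txas3\tcens3"
                 "\txa5\tcensa5\txa3\tcensa3\n")
        for idx, (site, pos1) in enumerate(zip(keep_rows, positions)):
            row = geno[site.id]
            carriers = [i for i in range(n) if row[i] == 1]
            k = len(carriers)
            tree = ts.at(site.position)
            carrier_count = {}
            cset = set(carriers)
            for c in carriers:
                u = c
                while u != -1:
                    carrier_count[u] = carrier_count.get(u, 0) + 1
                    u = tree.parent(u)
            if tree_fh is not None and idx < max_tree_sites:
                tree_fh.write(
                    "%d\t%s\n"
                    % (pos1, tree.as_newick(precision=10))
                )
            for c in carriers:
                tc, phi, node, sisters = copy_truth(tree, c, cset, carrier_count)
                if want_xas and k == 1:
                    # branch S is the edge above the sister leaf/clade root
                    x5, c5, x3, c3 = nearest_mut(
                        pos1, (c, sisters[0]), muts_by_node, L
                    )
                    a5, ca5, a3, ca3 = nearest_mut(pos1, (c,), muts_by_node, L)
                else:
                    x5, c5, x3, c3 = float("nan"), True, float("nan"), True
                    a5, ca5, a3, ca3 = float("nan"), True, float("nan"), True
                fh.write(
                    "%d\t%d\t%d\t%.10g\t%.10g\t%s\t%d\t%s\t%d\t%s\t%d\t%s\t%d\n"
                    % (pos1, c, k, tc, phi, x5, c5, x3, c3, a5, ca5, a3, ca3)
                )
    if tree_fh is not None:
        tree_fh.close()


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
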