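# Shared builders for test fixtures; everything is generated in code.

# tiny genotype matrix with known dosages and coordinates
tiny_genotypes <- function() {
  d <- matrix(c(0L, 1L, 2L,
                2L, NA, 0L,
                1L, 1L, 1L,
                0L, 0L, NA), nrow = 3L,
              dimnames = list(NULL, c("s1", "s2", "s3", "s4")))
  genotype_matrix(
    d,
    loci = data.frame(id = c("s1", "s2", "s3", "s4"),
                      chrom = c("chr1", "chr1", "chr2", "chr2"),
                      bp = c(100L, 200L, 100L, 300L),
                      stringsAsFactors = FALSE),
    samples = data.frame(id = c("a", "b", "c"),
                         cycle = c("C2", "C2", "C5"),
                         stringsAsFactors = FALSE),
    cycle_levels = c("C2", "C5"))
}

# genotype matrix with loci at specified pooled allele frequencies
geno_at_freqs <- function(n, p, cycle = "all") {
  d <- vapply(p, function(pp) rbinom(n, 2L, pp), integer(n))
  colnames(d) <- paste0("L", seq_along(p))
  genotype_matrix(d, samples = data.frame(id = paste0("i", seq_len(n)),
                                          cycle = cycle,
                                          stringsAsFactors = FALSE))
}

# balanced family-trial dataset and its ANOVA expected-mean-squares oracle
balanced_trial <- function(nf = 150L, e = 2L, r = 3L,
                           vc = c(G = 4, GE = 2, E = 6), seed = 1L) {
  set.seed(seed)
  g <- matrix(0L, nf, 1L, dimnames = list(sprintf("f%03d", seq_len(nf)), "L1"))
  simulate_phenotypes(g, n_env = e, n_rep = r, varcomps = vc,
                      env_sd = 1, rep_sd = 0.5)
}

# method-of-moments solution from expected mean squares on a balanced design:
# independent oracle for the REML fit (they coincide when interior)
ems_oracle <- function(pheno) {
  y <- pheno$value
  fam <- factor(pheno$family); env <- factor(pheno$environment)
  rp <- factor(pheno$replicate)
  nf <- nlevels(fam); e <- nlevels(env); r <- nlevels(rp)
  ybar_f <- tapply(y, fam, mean)
  ybar_fe <- tapply(y, list(fam, env), mean)
  ybar_e <- tapply(y, env, mean)
  ybar <- mean(y)
  ms_f <- e * r * sum((ybar_f - ybar)^2) / (nf - 1)
  ms_fe <- r * sum((ybar_fe - outer(ybar_f, ybar_e, "+") + ybar)^2) /
    ((nf - 1) * (e - 1))
  cellmean <- ybar_fe[cbind(as.integer(fam), as.integer(env))]
  repenv <- tapply(y, list(rp, env), mean)
  ms_err <- sum((y - cellmean -
                   (repenv[cbind(as.integer(rp), as.integer(env))] -
                      ybar_e[as.integer(env)]))^2) /
    ((nf - 1) * (e * r - 1) - (nf - 1) * (e - 1))
  c(G = (ms_f - ms_fe) / (e * r), GE = (ms_fe - ms_err) / r, E = ms_err)
}

# idealized Wright-Fisher protocol: per cycle, the only size-N sampling
# episode is the founder draw; the recombined population is made large so
# its sampling adds negligible drift
wf_protocol <- function(N, t, pop = 20000L) {
  cs <- cycle_spec(N, N, N, selfing_generations = 0L)
  breeding_protocol(rep(list(cs), t), recombination_scheme = "random_union",
                    next_cycle_pop_size = pop)
}

# a small VCF written from scratch
write_test_vcf <- function(path, extra_alt = FALSE) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB\tC",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t./.\t0|1\t1/1")
  if (extra_alt)
    lines <- c(lines, "1\t300\trs3\tG\tA,C\t.\tPASS\t.\tGT\t0/0\t0/1\t1/2")
  writeLines(lines, path)
  path
}
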