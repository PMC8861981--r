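# small in-code fixtures shared across test files

# a tiny two-sex study with known structure
tiny_study <- function(n_genes = 50L, seed = 1L, ...) {
  simulate_timecourse_study(sim_config(n_genes = n_genes, seed = seed, ...))
}

# annotation table for a 2 sexes x 5 ages x n_rep design
make_annotation <- function(n_rep = 4L, ages = c(3, 6, 9, 12, 18)) {
  df <- expand.grid(replicate = seq_len(n_rep), age_months = ages,
                    sex = c("M", "F"), stringsAsFactors = FALSE)
  df$sample_id <- sprintf("%s_%gm_r%d", df$sex, df$age_months, df$replicate)
  df[, c("sample_id", "sex", "age_months", "replicate")]
}

# random expression matrix matched to an annotation
random_matrix <- function(annot, n_genes = 20L, seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * nrow(annot), mean = 100, sd = 10),
              n_genes, nrow(annot),
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              annot$sample_id))
  attr(m, "scale") <- "linear"
  m
}

# cubic/quadratic design matrices on the scaled age axis, built
# independently of the package internals
design_X <- function(ages = c(3, 6, 9, 12, 18)) {
  s <- 2 * (ages - min(ages)) / diff(range(ages)) - 1
  outer(s, 0:3, `^`)
}
design_Z <- function(ages = c(3, 6, 9, 12, 18)) {
  s <- 2 * (ages - min(ages)) / diff(range(ages)) - 1
  outer(s, 0:2, `^`)
}

# dense multivariate-normal log-density via explicit covariance,
# determinant() and solve(): the oracle route for profile_loglik
mvn_loglik_oracle <- function(y, mu, Sigma) {
  d <- length(y)
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  -0.5 * (d * log(2 * pi) + ld +
            as.numeric(t(y - mu) %*% solve(Sigma) %*% (y - mu)))
}

# random PSD 3x3 matrix
random_psd3 <- function(scale = 0.1) {
  A <- matrix(rnorm(9, sd = scale), 3, 3)
  crossprod(A) + diag(1e-4, 3)
}

# a synthetic concordance partition with set sizes chosen by the caller
synthetic_partition <- function(n_common, n_discordant) {
  common <- sprintf("common_%04d", seq_len(n_common))
  disc <- sprintf("disc_%04d", seq_len(n_discordant))
  male <- c(setNames(rep(1L, n_common), common), setNames(rep(1L, n_discordant), disc))
  female <- c(setNames(rep(1L, n_common), common), setNames(rep(2L, n_discordant), disc))
  partition_genes(list(male = male, female = female))
}

# a 50-gene signed signature
toy_signature <- function(n = 50L) {
  setNames(rep(c(1L, -1L), length.out = n), sprintf("sig_%03d", seq_len(n)))
}
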