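# Shared fixtures, memoized so expensive builds and simulations run once per
# test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

fx_duplex_b <- function() memo("duplex_b", build_duplex(get_target("c-MYC_DS19"), helix_spec("B")))

fx_triplex <- function() memo("triplex", build_triplex(get_target("c-MYC_DS19"),
                                                       get_oligo("ON2-5'DNA"),
                                                       helix_spec("B")))

# 2000-frame synthetic triplex with one half-open Hoogsteen pair and
# independent frame sampling (flip_rate = 1), used for binomial parameter
# recovery; all other pairs stay closed.
fx_recovery_run <- function() {
  memo("recovery_run", {
    tx <- fx_triplex()
    reg <- pair_registry(tx)
    n_hg <- sum(reg$kind == "HG")
    p_open <- rep(0, n_hg)
    p_open[8] <- 0.5
    spec <- traj_spec(n_frames = 2000, seed = 101, p_open = p_open, flip_rate = 1)
    gen <- generate_trajectory(tx, spec)
    list(gen = gen, spec = spec, p_open = p_open)
  })
}

# random rigid motion with a fixed seed offset
rigid_case <- function(seed) {
  withr::with_seed(seed, {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 0, 2 * pi)
    list(R = lnahelix:::rotation_about(ax, ang), t = rnorm(3, sd = 25))
  })
}

# brute-force step twist: angle between successive C1'-C1' vectors projected
# onto the plane normal to the average base-pair normal (independent oracle
# for small duplexes)
brute_force_twist <- function(structure) {
  n <- max(structure$residue[structure$chain == "W"])
  c1 <- function(chain, res) {
    m <- structure[structure$chain == chain & structure$residue == res &
                   structure$atom == "C1'", ]
    c(m$x, m$y, m$z)
  }
  # pair normal from base frames
  zs <- vapply(seq_len(n), function(i) {
    fW <- base_reference_frame(structure, "W", i)
    fW$R[, 3]
  }, numeric(3))
  twists <- numeric(0)
  for (i in seq_len(n - 1)) {
    zm <- rowMeans(zs[, c(i, i + 1)])
    zm <- zm / sqrt(sum(zm^2))
    v1 <- c1("W", i) - c1("C", n + 1 - i)
    v2 <- c1("W", i + 1) - c1("C", n - i)
    p1 <- v1 - sum(v1 * zm) * zm
    p2 <- v2 - sum(v2 * zm) * zm
    ang <- atan2(sum(zm * c(p1[2] * p2[3] - p1[3] * p2[2],
                            p1[3] * p2[1] - p1[1] * p2[3],
                            p1[1] * p2[2] - p1[2] * p2[1])),
                 sum(p1 * p2)) * 180 / pi
    twists <- c(twists, ang)
  }
  twists
}

coords_matrix_of <- function(s) unname(as.matrix(s[, c("x", "y", "z")]))
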