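# The conditional spherical UNet denoiser. Convolution is defined on the
# 1-ring neighborhood of each vertex (7 taps: the vertex itself plus its ring
# in canonical azimuthal order; pentagons pad with the center). Downsampling
# keeps the order-prefix vertices, upsampling zero-pads the added vertices.
# Each level runs 2 ResBlocks whose activations are modulated (scale/shift)
# by a shared embedding of the time step, age and sex; self-attention over
# vertices runs at the coarsest levels. The gyral/sulcal mask enters by
# channel concatenation with the noisy input.
#
# Batches are block-stacked: B subjects on a V-vertex sphere form a (B*V) x C
# matrix, with all index structures offset per block. The forward pass is
# written against the autodiff ops, so the same code serves inference (plain
# matrices) and training (tracked parameters).

#' Denoiser configuration
#'
#' @param base_order Icosphere order of the model's input maps (6 at full
#'   resolution; 2 for desk-scale synthetic work).
#' @param feature_channels Number of per-vertex feature channels denoised
#'   (e.g. 2 for cortical thickness + shape index).
#' @param mask_channels Channels of the encoded anatomical mask concatenated
#'   to the input (1 for a binary gyral/sulcal mask encoded as -1/+1;
#'   0 disables anatomical conditioning).
#' @param n_levels UNet depth; level `l` lives on order `base_order - l + 1`.
#'   Must satisfy `n_levels <= base_order + 1`.
#' @param hidden_dims Width per level, length `n_levels` (128, 256, 512 at
#'   full scale).
#' @param resblocks_per_level Residual blocks per level (default 2).
#' @param attention_levels Level indices with vertex self-attention (default:
#'   the two coarsest).
#' @param time_embed_dim Dimension of the shared time/demographic embedding.
#' @return Object of class `denoiser_config`.
#' @export
denoiser_config <- function(base_order, feature_channels,
                            mask_channels = 1L,
                            n_levels = 3L,
                            hidden_dims = c(128L, 256L, 512L),
                            resblocks_per_level = 2L,
                            attention_levels = NULL,
                            time_embed_dim = 64L) {
  if (length(hidden_dims) != n_levels)
    stop("'hidden_dims' must have one width per level")
  if (n_levels > base_order + 1)
    stop("'n_levels' must be at most base_order + 1")
  if (is.null(attention_levels))
    attention_levels <- if (n_levels >= 2) c(n_levels - 1L, n_levels) else n_levels
  structure(list(
    base_order = as.integer(base_order),
    feature_channels = as.integer(feature_channels),
    mask_channels = as.integer(mask_channels),
    in_channels = as.integer(feature_channels + mask_channels),
    out_channels = as.integer(feature_channels),
    n_levels = as.integer(n_levels),
    hidden_dims = as.integer(hidden_dims),
    resblocks_per_level = as.integer(resblocks_per_level),
    attention_levels = as.integer(attention_levels),
    time_embed_dim = as.integer(time_embed_dim)
  ), class = "denoiser_config")
}

#' @export
print.denoiser_config <- function(x, ...) {
  cat(sprintf(
    "Spherical UNet config: order %d input, %d+%d channels, levels [%s], attention at {%s}\n",
    x$base_order, x$feature_channels, x$mask_channels,
    paste(x$hidden_dims, collapse = ", "),
    paste(x$attention_levels, collapse = ", ")))
  invisible(x)
}

# Per-level geometry: 7-tap gather index (self first, then the canonical ring,
# pentagon pad = self) and vertex counts, for orders base_order .. down.
denoiser_geometry <- function(config) {
  lapply(seq_len(config$n_levels), function(l) {
    ord <- config$base_order - l + 1L
    ico <- ico_sphere(ord)
    conv_idx <- cbind(seq_len(nrow(ico$vertices)), ico$neighbor_table)
    list(order = ord, V = nrow(ico$vertices), conv_idx = conv_idx)
  })
}

# Block-offset a per-vertex index column for a batch of B stacked subjects.
batch_index <- function(idx, V, B) {
  as.vector(outer(idx, (seq_len(B) - 1L) * V, `+`))
}

#' Spherical 1-ring convolution
#'
#' For each vertex, gathers the 7 taps (the vertex, then its ring neighbors in
#' canonical azimuthal order; the 12 pentagons repeat the center as a pad) and
#' contracts them with the kernel.
#'
#' @param features V x C_in matrix of per-vertex features.
#' @param ico The `ico_sphere` the features live on.
#' @param weights Kernel, either a 3-D array of shape (C_out, C_in, 7) or the
#'   flat (7 * C_in) x C_out matrix used internally.
#' @param bias Length-C_out bias (default 0).
#' @return V x C_out matrix.
#' @export
spherical_conv <- function(features, ico, weights, bias = NULL) {
  features <- as_vertex_matrix(features)
  if (nrow(features) != nrow(ico$vertices))
    stop("feature rows must match the sphere's vertex count")
  cin <- ncol(features)
  if (length(dim(weights)) == 3) {
    stopifnot(dim(weights)[2] == cin, dim(weights)[3] == 7)
    weights <- flatten_kernel(weights)
  }
  if (nrow(weights) != 7 * cin) stop("kernel/in-channel mismatch")
  idx <- cbind(seq_len(nrow(features)), ico$neighbor_table)
  g <- do.call(cbind, lapply(1:7, function(k) features[idx[, k], , drop = FALSE]))
  out <- g %*% weights
  if (!is.null(bias)) out <- sweep(out, 2, bias, `+`)
  out
}

# (C_out, C_in, 7) array -> (7*C_in) x C_out matrix matching the tap-major
# gather layout [tap1 ch1..C, tap2 ch1..C, ...].
flatten_kernel <- function(w) {
  cout <- dim(w)[1]; cin <- dim(w)[2]
  flat <- matrix(0, 7 * cin, cout)
  for (k in 1:7) for (ci in seq_len(cin))
    flat[(k - 1) * cin + ci, ] <- w[, ci, k]
  flat
}

#' Sinusoidal time-step encoding
#'
#' Standard geometric-frequency ladder: half the dimensions are
#' \eqn{\sin(t \omega_i)}, half \eqn{\cos(t \omega_i)} with
#' \eqn{\omega_i = 10000^{-i/(d/2-1)}}, so periods range from \eqn{2\pi} up to
#' \eqn{2\pi \cdot 10^4} (covering any practical step count). The fitted
#' denoiser passes this encoding through a learned two-layer perceptron.
#'
#' @param t Vector of (integer) time steps.
#' @param dim Even embedding dimension.
#' @return length(t) x dim matrix.
#' @export
time_embedding <- function(t, dim) {
  if (dim %% 2 != 0) stop("'dim' must be even")
  half <- dim / 2
  freqs <- 10000^(-(0:(half - 1)) / (half - 1))
  ang <- outer(t, freqs)
  cbind(sin(ang), cos(ang))
}

# ---- parameter construction -------------------------------------------------

rand_mat <- function(nr, nc) matrix(rnorm(nr * nc) / sqrt(nr), nr, nc)
zero_mat <- function(nr, nc) matrix(0, nr, nc)

conv_params <- function(p, name, cin, cout) {
  p[[paste0(name, "_W")]] <- rand_mat(7 * cin, cout)
  p[[paste0(name, "_b")]] <- zero_mat(1, cout)
  p
}

norm_params <- function(p, name, c) {
  p[[paste0(name, "_g")]] <- matrix(1, 1, c)
  p[[paste0(name, "_b")]] <- zero_mat(1, c)
  p
}

resblock_params <- function(p, name, cin, cout, emb_dim) {
  p <- norm_params(p, paste0(name, "_n1"), cin)
  p <- conv_params(p, paste0(name, "_c1"), cin, cout)
  p <- norm_params(p, paste0(name, "_n2"), cout)
  p[[paste0(name, "_film_W")]] <- zero_mat(emb_dim, 2 * cout)
  p[[paste0(name, "_film_b")]] <- zero_mat(1, 2 * cout)
  p <- conv_params(p, paste0(name, "_c2"), cout, cout)
  if (cin != cout) p[[paste0(name, "_skip_W")]] <- rand_mat(cin, cout)
  p
}

attn_params <- function(p, name, c) {
  p <- norm_params(p, paste0(name, "_n"), c)
  p[[paste0(name, "_Wq")]] <- rand_mat(c, c)
  p[[paste0(name, "_Wk")]] <- rand_mat(c, c)
  p[[paste0(name, "_Wv")]] <- rand_mat(c, c)
  p[[paste0(name, "_Wo")]] <- zero_mat(c, c)
  p
}

#' Initialize denoiser parameters
#'
#' Fan-in-scaled Gaussian weights; the final output convolution, the FiLM
#' projections and attention output projections start at zero so the network
#' is the identity-to-zero map at initialization (stable early training).
#'
#' @param config A `denoiser_config`.
#' @param seed Integer seed; initialization is deterministic given it.
#' @return Named list of parameter matrices.
#' @export
init_denoiser_params <- function(config, seed = 1L) {
  with_seed_(seed, {
    d <- config$time_embed_dim
    hd <- config$hidden_dims
    L <- config$n_levels
    p <- list()
    # embedding MLPs: time (sinusoidal -> d -> d), age (1 -> d -> d), sex idem
    p$temb_W1 <- rand_mat(d, d); p$temb_b1 <- zero_mat(1, d)
    p$temb_W2 <- rand_mat(d, d); p$temb_b2 <- zero_mat(1, d)
    p$age_W1 <- rand_mat(1, d);  p$age_b1 <- zero_mat(1, d)
    p$age_W2 <- rand_mat(d, d);  p$age_b2 <- zero_mat(1, d)
    p$sex_W1 <- rand_mat(1, d);  p$sex_b1 <- zero_mat(1, d)
    p$sex_W2 <- rand_mat(d, d);  p$sex_b2 <- zero_mat(1, d)

    p <- conv_params(p, "stem", config$in_channels, hd[1])
    for (l in seq_len(L)) {
      cin <- if (l == 1) hd[1] else hd[l - 1]
      for (r in seq_len(config$resblocks_per_level)) {
        p <- resblock_params(p, sprintf("enc%d_rb%d", l, r),
                             if (r == 1) cin else hd[l], hd[l], d)
      }
      if (l %in% config$attention_levels)
        p <- attn_params(p, sprintf("enc%d_attn", l), hd[l])
    }
    for (l in seq(L - 1, 1)) {
      if (L < 2) break
      cin <- hd[l + 1] + hd[l]   # unpooled bottom + skip
      for (r in seq_len(config$resblocks_per_level)) {
        p <- resblock_params(p, sprintf("dec%d_rb%d", l, r),
                             if (r == 1) cin else hd[l], hd[l], d)
      }
      if (l %in% config$attention_levels)
        p <- attn_params(p, sprintf("dec%d_attn", l), hd[l])
    }
    p <- norm_params(p, "out_n", hd[1])
    p$out_W <- zero_mat(7 * hd[1], config$out_channels)
    p$out_b <- zero_mat(1, config$out_channels)
    p
  })
}

# ---- forward pass -----------------------------------------------------------

fwd_norm <- function(x, p, name) {
  ad_channelnorm(x, p[[paste0(name, "_g")]], p[[paste0(name, "_b")]])
}

fwd_conv <- function(x, p, name, idx7) {
  ad_sphconv(x, p[[paste0(name, "_W")]], p[[paste0(name, "_b")]], idx7)
}

fwd_resblock <- function(x, emb_rows, p, name, idx7) {
  h <- fwd_conv(ad_silu(fwd_norm(x, p, paste0(name, "_n1"))), p,
                paste0(name, "_c1"), idx7)
  cout <- ncol(ad_value(h))
  film <- ad_add(ad_mm(emb_rows, p[[paste0(name, "_film_W")]]),
                 p[[paste0(name, "_film_b")]])
  scale <- ad_cols(film, seq_len(cout))
  shift <- ad_cols(film, cout + seq_len(cout))
  h <- fwd_norm(h, p, paste0(name, "_n2"))
  h <- ad_add(ad_add(h, ad_mul(h, scale)), shift)   # h * (1 + scale) + shift
  h <- fwd_conv(ad_silu(h), p, paste0(name, "_c2"), idx7)
  skW <- p[[paste0(name, "_skip_W")]]
  skip <- if (is.null(skW)) x else ad_mm(x, skW)
  ad_add(h, skip)
}

fwd_attention <- function(x, p, name, V, B) {
  n <- fwd_norm(x, p, paste0(name, "_n"))
  c <- ncol(ad_value(x))
  q <- ad_mm(n, p[[paste0(name, "_Wq")]])
  k <- ad_mm(n, p[[paste0(name, "_Wk")]])
  v <- ad_mm(n, p[[paste0(name, "_Wv")]])
  blocks <- lapply(seq_len(B), function(b) {
    rows <- (b - 1L) * V + seq_len(V)
    qb <- ad_gather(q, rows); kb <- ad_gather(k, rows); vb <- ad_gather(v, rows)
    a <- ad_softmax_rows(ad_scale(ad_mm(qb, ad_t(kb)), 1 / sqrt(c)))
    ad_mm(a, vb)
  })
  o <- if (B == 1) blocks[[1]] else ad_rbind(blocks)
  ad_add(x, ad_mm(o, p[[paste0(name, "_Wo")]]))
}

# Shared embedding of (t, age, sex): sinusoidal t through a 2-layer MLP, plus
# one small MLP per covariate, summed. Rows = batch items.
fwd_embedding <- function(p, t_vec, age, sex) {
  d <- ncol(ad_value(p$temb_W1))
  te <- time_embedding(t_vec, d)
  h <- ad_add(ad_mm(ad_silu(ad_add(ad_mm(te, p$temb_W1), p$temb_b1)),
                    p$temb_W2), p$temb_b2)
  ae <- ad_add(ad_mm(ad_silu(ad_add(ad_mm(matrix(age, ncol = 1), p$age_W1),
                                    p$age_b1)), p$age_W2), p$age_b2)
  se <- ad_add(ad_mm(ad_silu(ad_add(ad_mm(matrix(sex, ncol = 1), p$sex_W1),
                                    p$sex_b1)), p$sex_W2), p$sex_b2)
  ad_silu(ad_add(ad_add(h, ae), se))
}

#' Demographic embedding vectors
#'
#' Passes age and sex through their per-covariate perceptrons and returns the
#' vectors that are added to the time embedding inside the denoiser.
#' @param age Numeric vector, age/100 per batch item.
#' @param sex Numeric vector in \{0, 1\} (female 0, male 1).
#' @param params Denoiser parameter list (for the MLP weights).
#' @return length(age) x time_embed_dim matrix.
#' @export
demographic_embedding <- function(age, sex, params) {
  ae <- ad_value(ad_add(ad_mm(ad_silu(ad_add(ad_mm(matrix(age, ncol = 1),
        params$age_W1), params$age_b1)), params$age_W2), params$age_b2))
  se <- ad_value(ad_add(ad_mm(ad_silu(ad_add(ad_mm(matrix(sex, ncol = 1),
        params$sex_W1), params$sex_b1)), params$sex_W2), params$sex_b2))
  ae + se
}

#' Conditional spherical UNet forward pass
#'
#' Predicts the velocity for a block-stacked batch of noisy maps. The encoded
#' anatomical mask is concatenated to the input channels; the time step, age
#' and sex enter through the shared embedding that modulates every ResBlock.
#'
#' @param params Parameter list from [init_denoiser_params()] (plain matrices
#'   for inference, or `adnode`s during training).
#' @param config The `denoiser_config`.
#' @param geom Geometry from `denoiser_geometry(config)` (built internally if
#'   `NULL`).
#' @param x (B*V) x feature_channels matrix of noisy maps, B subjects stacked.
#' @param t_vec Time step per batch item (length B, or scalar recycled).
#' @param age,sex Length-B conditioning covariates (age/100 and 0/1).
#' @param mask (B*V) x mask_channels encoded mask, or `NULL` when
#'   `mask_channels = 0`.
#' @return (B*V) x out_channels predicted velocity (an `adnode` when any
#'   parameter is tracked).
#' @export
denoiser_forward <- function(params, config, geom = NULL, x, t_vec, age, sex,
                             mask = NULL) {
  if (is.null(geom)) geom <- denoiser_geometry(config)
  V1 <- geom[[1]]$V
  nr <- nrow(ad_value(x))
  if (nr %% V1 != 0) stop("input rows are not a multiple of the base vertex count")
  B <- nr %/% V1
  t_vec <- rep_len(t_vec, B); age <- rep_len(age, B); sex <- rep_len(sex, B)
  if (config$mask_channels > 0) {
    if (is.null(mask)) stop("config expects a mask but none was given")
    h_in <- ad_cbind(list(x, mask))
  } else h_in <- x
  # per-level batched 7-tap indices and pool/unpool index vectors
  idx7 <- lapply(geom, function(gl)
    lapply(1:7, function(k) batch_index(gl$conv_idx[, k], gl$V, B)))
  emb <- fwd_embedding(params, t_vec, age, sex)
  L <- config$n_levels
  p <- params

  expand_emb <- function(V) ad_gather(emb, rep(seq_len(B), each = V))

  h <- fwd_conv(h_in, p, "stem", idx7[[1]])
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    er <- expand_emb(geom[[l]]$V)
    for (r in seq_len(config$resblocks_per_level))
      h <- fwd_resblock(h, er, p, sprintf("enc%d_rb%d", l, r), idx7[[l]])
    if (l %in% config$attention_levels)
      h <- fwd_attention(h, p, sprintf("enc%d_attn", l), geom[[l]]$V, B)
    skips[[l]] <- h
    if (l < L) {   # order-prefix pooling on each block
      keep <- batch_index(seq_len(geom[[l + 1]]$V), geom[[l]]$V, B)
      h <- ad_gather(h, keep)
    }
  }
  if (L >= 2) for (l in seq(L - 1, 1)) {
    put <- batch_index(seq_len(geom[[l + 1]]$V), geom[[l]]$V, B)
    h <- ad_scatter(h, put, B * geom[[l]]$V)      # zero-pad up-pooling
    h <- ad_cbind(list(h, skips[[l]]))
    er <- expand_emb(geom[[l]]$V)
    for (r in seq_len(config$resblocks_per_level))
      h <- fwd_resblock(h, er, p, sprintf("dec%d_rb%d", l, r), idx7[[l]])
    if (l %in% config$attention_levels)
      h <- fwd_attention(h, p, sprintf("dec%d_attn", l), geom[[l]]$V, B)
  }
  h <- ad_silu(fwd_norm(h, p, "out_n"))
  ad_sphconv(h, p$out_W, p$out_b, idx7[[1]])
}
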