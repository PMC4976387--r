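#' Configuration of a synthetic multi-round labeling scene
#'
#' Collects the generative parameters behind the simulated specimen: a field
#' of punctate epitope sites, a subset of which cluster into shared
#' "domains" that induce multi-channel colocalization, imaged over repeated
#' label/image/elute cycles with stochastic per-round labeling, residual
#' post-elution signal, a multiplicative round-over-round gain (antigen
#' retrieval), rigid stage drift, a smooth low-frequency background and
#' additive Gaussian noise.
#'
#' @param image_shape integer vector `(rows, cols)` of the output images.
#' @param n_sites number of domain-associated epitope sites. When
#'   `n_domains == 0` this is ignored and only background sites are placed.
#' @param n_domains number of colocalization domains. Domain centers are
#'   uniform over the image; member sites scatter around their center with
#'   standard deviation `domain_sigma`.
#' @param channel_affinities numeric vector, one probability per channel:
#'   the chance that a domain site carries that channel's epitope,
#'   conditionally independent across channels given the domain.
#' @param background_site_rate number of additional independent
#'   (single-channel) sites placed per channel, uniformly over the image.
#' @param label_prob per-round probability that an available epitope is
#'   actually labeled; this is the source of the stochastic round-to-round
#'   labeling differences the minmax analysis visualises.
#' @param residual_fraction expected fraction of a round's punctate signal
#'   that survives simulated antibody elution, in `[0, 1)`.
#' @param round_gain multiplicative intensity factor applied per successive
#'   round (`round_gain^(round-1)`), emulating incidental antigen retrieval.
#' @param psf_sigma Gaussian point-spread width in pixels.
#' @param spot_amplitude peak intensity of one labeled site in round 1, in
#'   16-bit intensity units.
#' @param noise_sigma additive Gaussian noise standard deviation
#'   (intensity units); 0 disables noise.
#' @param background_amplitude amplitude of the smooth low-frequency
#'   background field (intensity units); 0 disables it. Each channel gets
#'   its own independent field, constant across rounds.
#' @param drift_per_round rigid `(dy, dx)` translation in pixels applied
#'   cumulatively per round (round r is shifted by `(r-1) * drift_per_round`).
#' @param domain_sigma scatter (pixels) of member sites around their domain
#'   center.
#' @param seed integer root seed; identical configuration and seed give
#'   bit-identical scenes and images.
#'
#' @return An object of class `scene_config`.
#' @seealso [generate_scene()], [render_round()], [simulate_dataset()]
#' @export
scene_config <- function(image_shape = c(256L, 256L),
                         n_sites = 300L,
                         n_domains = 40L,
                         channel_affinities = c(0.9, 0.9, 0.9),
                         background_site_rate = 60L,
                         label_prob = 0.9,
                         residual_fraction = 0.055,
                         round_gain = 1.15,
                         psf_sigma = 1.5,
                         spot_amplitude = 12000,
                         noise_sigma = 40,
                         background_amplitude = 1500,
                         drift_per_round = c(2, -1),
                         domain_sigma = 2,
                         seed = 1L) {
  if (length(image_shape) != 2 || any(image_shape < 1)) {
    stop("configuration error: image_shape must be two positive integers")
  }
  check_probability(channel_affinities, "channel_affinities")
  check_probability(label_prob, "label_prob")
  check_probability(residual_fraction, "residual_fraction")
  if (residual_fraction >= 1) {
    stop("configuration error: residual_fraction must lie in [0, 1)")
  }
  if (psf_sigma <= 0) stop("configuration error: psf_sigma must be > 0")
  if (n_sites < 0 || n_domains < 0 || background_site_rate < 0) {
    stop("configuration error: counts must be non-negative")
  }
  if (noise_sigma < 0 || background_amplitude < 0 || spot_amplitude <= 0) {
    stop("configuration error: amplitudes must be non-negative")
  }
  if (length(drift_per_round) != 2) {
    stop("configuration error: drift_per_round must be (dy, dx)")
  }
  structure(list(
    image_shape = as.integer(image_shape),
    n_sites = as.integer(n_sites),
    n_domains = as.integer(n_domains),
    channel_affinities = channel_affinities,
    background_site_rate = as.integer(background_site_rate),
    label_prob = label_prob,
    residual_fraction = residual_fraction,
    round_gain = round_gain,
    psf_sigma = psf_sigma,
    spot_amplitude = spot_amplitude,
    noise_sigma = noise_sigma,
    background_amplitude = background_amplitude,
    drift_per_round = as.numeric(drift_per_round),
    domain_sigma = domain_sigma,
    seed = as.integer(seed)
  ), class = "scene_config")
}

#' Realize a synthetic epitope scene
#'
#' Draws site coordinates and per-channel epitope memberships from a
#' [scene_config()]. Domain sites are placed by sampling a domain center
#' uniformly over the image and scattering members around it; each domain
#' site carries channel `c`'s epitope with probability
#' `channel_affinities[c]`, independently across channels. Background sites
#' belong to exactly one channel.
#'
#' @param config a [scene_config()].
#' @return An object of class `scene` with elements `positions` (n x 2
#'   subpixel row/col coordinates), `membership` (n x k logical matrix),
#'   `domain` (integer domain index, `NA` for background sites) and
#'   `n_channels`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  k <- length(config$channel_affinities)
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  with_seed(derive_seed(config$seed, "scene"), {
    pos <- matrix(numeric(0), 0, 2)
    member <- matrix(logical(0), 0, k)
    domain <- integer(0)
    if (config$n_domains > 0 && config$n_sites > 0) {
      centers <- cbind(runif(config$n_domains, 1, nr),
                       runif(config$n_domains, 1, nc))
      assign_d <- sample.int(config$n_domains, config$n_sites, replace = TRUE)
      p <- centers[assign_d, , drop = FALSE] +
        matrix(rnorm(2 * config$n_sites, sd = config$domain_sigma),
               ncol = 2)
      p[, 1] <- pmin(pmax(p[, 1], 1), nr)
      p[, 2] <- pmin(pmax(p[, 2], 1), nc)
      m <- matrix(runif(config$n_sites * k), ncol = k)
      m <- sweep(m, 2, config$channel_affinities, "<")
      pos <- rbind(pos, p)
      member <- rbind(member, m)
      domain <- c(domain, assign_d)
    }
    if (config$background_site_rate > 0) {
      for (ch in seq_len(k)) {
        nb <- config$background_site_rate
        p <- cbind(runif(nb, 1, nr), runif(nb, 1, nc))
        m <- matrix(FALSE, nb, k); m[, ch] <- TRUE
        pos <- rbind(pos, p)
        member <- rbind(member, m)
        domain <- c(domain, rep(NA_integer_, nb))
      }
    }
    structure(list(positions = pos, membership = member, domain = domain,
                   n_channels = k), class = "scene")
  })
}

# Indices of sites whose label survives the round's draws: available sites
# (epitope membership) are labeled with probability label_prob; after
# elution each labeled site additionally survives with probability
# residual_fraction. The labeling draw is shared between the pre- and
# post-elution renderings of a round.
labeled_sites <- function(scene, config, round_index, channel,
                          post_elution = FALSE) {
  avail <- which(scene$membership[, channel])
  labeled <- with_seed(derive_seed(config$seed, "label", round_index, channel), {
    avail[runif(length(avail)) < config$label_prob]
  })
  if (!post_elution) return(labeled)
  with_seed(derive_seed(config$seed, "elute", round_index, channel), {
    labeled[runif(length(labeled)) < config$residual_fraction]
  })
}

# Additive rendering of Gaussian spots; separable kernel per site on a
# local window so cost is O(sites * window^2).
render_spots <- function(shape, positions, amplitude, sigma) {
  img <- matrix(0, shape[1], shape[2])
  if (nrow(positions) == 0) return(img)
  w <- ceiling(4 * sigma)
  for (i in seq_len(nrow(positions))) {
    pr <- positions[i, 1]; pc <- positions[i, 2]
    rr <- max(1, floor(pr - w)):min(shape[1], ceiling(pr + w))
    cc <- max(1, floor(pc - w)):min(shape[2], ceiling(pc + w))
    if (!length(rr) || !length(cc)) next
    gr <- exp(-(rr - pr)^2 / (2 * sigma^2))
    gc <- exp(-(cc - pc)^2 / (2 * sigma^2))
    img[rr, cc] <- img[rr, cc] + amplitude * (gr %o% gc)
  }
  img
}

smooth_background <- function(config, channel) {
  if (config$background_amplitude <= 0) {
    return(matrix(0, config$image_shape[1], config$image_shape[2]))
  }
  with_seed(derive_seed(config$seed, "background", channel), {
    coarse <- matrix(runif(9), 3, 3)
    field <- resize_bilinear(coarse, config$image_shape)
    config$background_amplitude * field
  })
}

#' Render one imaging round of a synthetic scene
#'
#' For every channel, each site carrying that channel's epitope is labeled
#' independently with probability `label_prob`; labeled sites are rendered
#' as Gaussian spots of width `psf_sigma`, with amplitude
#' `spot_amplitude * round_gain^(round_index - 1)` and a cumulative rigid
#' drift of `(round_index - 1) * drift_per_round`. A static smooth
#' background field and additive Gaussian noise are then applied and values
#' are clipped to the 16-bit range `[0, 65535]`.
#'
#' With `post_elution = TRUE` the same labeled set is thinned: each labeled
#' site survives elution independently with probability
#' `residual_fraction`, so the expected residual punctate signal is that
#' fraction of the pre-elution round.
#'
#' @param scene a [generate_scene()] result.
#' @param config the [scene_config()] used to generate `scene`.
#' @param round_index imaging round, 1-based.
#' @param post_elution render the residual image after simulated antibody
#'   elution instead of the labeled image.
#' @return Named list of numeric matrices, one per channel (`ch1`, ...).
#' @export
render_round <- function(scene, config, round_index, post_elution = FALSE) {
  stopifnot(inherits(scene, "scene"), inherits(config, "scene_config"))
  if (round_index < 1) stop("round_index must be >= 1")
  k <- scene$n_channels
  shape <- config$image_shape
  drift <- (round_index - 1) * config$drift_per_round
  amp <- config$spot_amplitude * config$round_gain^(round_index - 1)
  out <- vector("list", k)
  names(out) <- paste0("ch", seq_len(k))
  for (ch in seq_len(k)) {
    keep <- labeled_sites(scene, config, round_index, ch, post_elution)
    pos <- scene$positions[keep, , drop = FALSE]
    if (nrow(pos)) {
      pos[, 1] <- pos[, 1] + drift[1]
      pos[, 2] <- pos[, 2] + drift[2]
    }
    img <- render_spots(shape, pos, amp, config$psf_sigma)
    img <- img + smooth_background(config, ch)
    if (config$noise_sigma > 0) {
      img <- img + with_seed(
        derive_seed(config$seed, "noise", round_index, ch, as.integer(post_elution)),
        matrix(rnorm(prod(shape), sd = config$noise_sigma), shape[1], shape[2]))
    }
    out[[ch]] <- pmin(pmax(img, 0), 65535)
  }
  out
}

#' Simulate a full multi-round dataset
#'
#' Renders `n_rounds` imaging rounds of one scene and assembles them into a
#' [multiround_dataset()]. Optionally renders the post-elution residual
#' image of each round as well (returned separately, since elution images
#' are compared against their own round, not stacked with the labeled
#' rounds).
#'
#' @param config a [scene_config()].
#' @param n_rounds number of labeled imaging rounds.
#' @param post_elution also render residual post-elution images per round.
#' @param labels optional channel label strings (antibody names).
#' @return A list with `dataset` (a `multiround_dataset`), `scene`, and,
#'   when requested, `post_elution` (list indexed by round of per-channel
#'   images).
#' @export
simulate_dataset <- function(config, n_rounds = 3, post_elution = FALSE,
                             labels = NULL) {
  scene <- generate_scene(config)
  k <- scene$n_channels
  channels <- paste0("ch", seq_len(k))
  images <- list()
  for (r in seq_len(n_rounds)) {
    imgs <- render_round(scene, config, r)
    for (ch in seq_len(k)) {
      images[[dataset_key(r, channels[ch])]] <- imgs[[ch]]
    }
  }
  ds <- multiround_dataset(images, labels = labels)
  out <- list(dataset = ds, scene = scene)
  if (post_elution) {
    out$post_elution <- lapply(seq_len(n_rounds), function(r) {
      render_round(scene, config, r, post_elution = TRUE)
    })
  }
  out
}
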