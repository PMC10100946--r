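#' Build the full invasion report for a merged MSP table
#'
#' One-stop composition of the niche/invasion analytics: assigns niches from
#' the baselines, computes the niche-split richness/abundance series, the
#' oral-invader detection tables, and (per donor, when at least three
#' invaders exist) the Spearman correlation between each invader's abundance
#' in the last enriched-saliva sample and in the last mucosal sample.
#'
#' @param merged A *normalized* merged [msp_table()].
#' @param meta Sample metadata tibble.
#' @param niches Optional pre-computed [assign_niches()] result.
#' @param first_injection_day First saliva injection day (default 9).
#' @return An object of class `oralgut_invasion_report`: a list with
#'   `niches`, `series`, `invader_matrix`, `invader_summary`,
#'   `correlations` and `first_injection_day`.
#' @export
invasion_report <- function(merged, meta, niches = NULL,
                            first_injection_day = 9) {
  meta <- as_tibble(meta)
  if (is.null(niches)) {
    niches <- assign_niches(merged, meta)
  }
  series <- niche_series(merged, niches, meta)
  inv <- detect_oral_invaders(merged, niches, meta, first_injection_day)

  cors <- list(tibble(
    donor = character(), source = character(), target = character(),
    rho = double(), p_value = double(), n = integer()
  ))
  for (d in unique(meta$donor)) {
    im <- inv$invader_matrix
    invaders <- unique(im$msp_id[im$donor == d])
    md <- meta[meta$donor == d, ]
    enr <- md[md$sample_type == "enriched_saliva", ]
    muc <- md[md$sample_type == "mucosal", ]
    if (length(invaders) >= 3 && nrow(enr) > 0 && nrow(muc) > 0) {
      src <- enr$sample_id[which.max(enr$day)]
      tgt <- muc$sample_id[which.max(muc$day)]
      cors[[d]] <- invader_correlation(merged, src, tgt, invaders) |>
        mutate(donor = d, .before = 1)
    }
  }
  structure(
    list(
      niches = niches, series = series,
      invader_matrix = inv$invader_matrix,
      invader_summary = inv$invader_summary,
      correlations = bind_rows(cors),
      first_injection_day = first_injection_day
    ),
    class = "oralgut_invasion_report"
  )
}

#' @describeIn invasion_report Long tibble of the invader detection matrix
#'   (one row per invader MSP x bioreactor sample).
#' @param x An invasion report.
#' @param ... Unused.
#' @method tidy oralgut_invasion_report
#' @export
tidy.oralgut_invasion_report <- function(x, ...) {
  x$invader_matrix
}

#' @describeIn invasion_report One row per donor: oral/gut/ND species
#'   totals, number of invaders, pre-existing invaders, and the post-
#'   injection mucosal and luminal oral-invader counts.
#' @method glance oralgut_invasion_report
#' @export
glance.oralgut_invasion_report <- function(x, ...) {
  out <- list()
  for (d in unique(x$niches$donor)) {
    nd <- x$niches[x$niches$donor == d, ]
    im <- x$invader_matrix[x$invader_matrix$donor == d, , drop = FALSE]
    sm <- x$invader_summary[x$invader_summary$donor == d, ]
    post <- sm[sm$phase == "post", ]
    post_count <- function(type) {
      ids <- unique(im$msp_id[im$sample_type == type &
                                im$day >= x$first_injection_day &
                                im$abundance > 0])
      length(ids)
    }
    rho <- if (nrow(x$correlations) > 0 && d %in% x$correlations$donor) {
      x$correlations$rho[x$correlations$donor == d][1]
    } else {
      NA_real_
    }
    out[[d]] <- tibble(
      donor = d,
      n_msp = nrow(nd),
      n_gut = sum(nd$niche == "gut"),
      n_oral = sum(nd$niche == "oral"),
      n_nd = sum(nd$niche == "ND"),
      n_invaders = length(unique(im$msp_id)),
      n_pre_existing = length(unique(im$msp_id[im$pre_existing])),
      mucosal_oral_post = post_count("mucosal"),
      luminal_oral_post = post_count("luminal"),
      max_mucosal_oral = if (nrow(post) > 0) {
        max(c(post$n_oral_detected[post$sample_type == "mucosal"], 0L))
      } else 0L,
      rho_saliva_mucosa = rho
    )
  }
  bind_rows(out)
}

#' @describeIn invasion_report Human-readable summary of the report: niche
#'   counts and the luminal-vs-mucosal oral-invader contrast, printed from
#'   the report's own fields without recomputation.
#' @param object An invasion report.
#' @export
summary.oralgut_invasion_report <- function(object, ...) {
  g <- glance(object)
  lines <- character(0)
  for (i in seq_len(nrow(g))) {
    r <- g[i, ]
    lines <- c(lines, paste0(
      "Donor ", r$donor, ": ", r$n_msp, " MSPs (",
      r$n_gut, " gut / ", r$n_oral, " oral / ", r$n_nd, " ND)"
    ))
    if (r$n_invaders == 0) {
      lines <- c(lines, "  no oral invaders detected")
    } else {
      lines <- c(lines, paste0(
        "  oral invaders: ", r$n_invaders,
        " (", r$n_pre_existing, " pre-existing); post-injection ",
        r$mucosal_oral_post, " mucosal vs ", r$luminal_oral_post, " luminal"
      ))
      if (!is.na(r$rho_saliva_mucosa)) {
        lines <- c(lines, paste0(
          "  Spearman rho (enriched saliva vs mucosa): ",
          signif(r$rho_saliva_mucosa, 3)
        ))
      }
    }
  }
  sm <- object$invader_summary
  for (i in seq_len(nrow(sm))) {
    lines <- c(lines, paste0(
      "  ", sm$donor[i], " ", sm$sample_type[i], "@d", sm$day[i],
      " [", sm$phase[i], "]: ", sm$n_oral_detected[i], " oral MSPs"
    ))
  }
  structure(lines, class = "oralgut_invasion_summary")
}

#' @export
print.oralgut_invasion_summary <- function(x, ...) {
  cat(paste(unclass(x), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.oralgut_invasion_report <- function(x, ...) {
  cat("<oralgut invasion report>\n")
  print(summary(x))
  invisible(x)
}
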