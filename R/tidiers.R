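# broom-style tidy()/glance() methods.

#' @export
tidy.contact_summary <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "contact_summary")
  out
}

#' @export
glance.contact_summary <- function(x, ...) {
  tibble(n_residues = nrow(x), n_frames = attr(x, "n_frames"),
         mean_p_contact = mean(x$p_contact),
         n_stable_50 = sum(x$p_contact > 0.5),
         n_stable_80 = sum(x$p_contact > 0.8))
}

#' @export
tidy.residence_summary <- function(x, ...) x$events

#' @export
glance.residence_summary <- function(x, ...) {
  tibble(n_events = nrow(x$events),
         n_long = x$n_long,
         min_event_ps = x$min_event_ps,
         t_res_max_ps = if (nrow(x$events)) max(x$events$t_res_ps) else NA_real_,
         t_res_sum_ps = sum(x$events$t_res_ps),
         mean_dwell_ps = x$mean_dwell_ps)
}

#' @export
tidy.rdf_profile <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "rdf_profile")
  out
}

#' @export
glance.rdf_profile <- function(x, ...) {
  tibble(species = attr(x, "species"), dr = attr(x, "dr"),
         n_ref = attr(x, "n_ref"), n_frames = attr(x, "n_frames"),
         g_max = max(x$g, na.rm = TRUE),
         r_at_g_max = x$r[which.max(x$g)])
}

#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(species = x$species, local_fraction = x$local_fraction,
         global_fraction = x$global_fraction, mean_near = x$mean_near,
         n_frames = x$n_frames, undefined = x$undefined)
}

#' @export
tidy.residue_classification <- function(x, ...) {
  tibble(class = names(x$fractions), fraction = unname(x$fractions),
         group = x$group, n = x$n)
}

#' @export
glance.residue_classification <- function(x, ...) {
  tibble(group = x$group, n = x$n,
         basic = unname(x$fractions["basic"]),
         aromatic_hydrophobic = unname(x$fractions["aromatic"] +
                                         x$fractions["hydrophobic"]))
}
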