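# shared fixtures, built once per test run

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):2,C:3);")

# small synthetic dataset reused across module tests
fix <- synth_dataset(synth_config(n_lakes = 40, n_events = 250, seed = 11))

# three-lake toy world with hand-controllable distances
toy_world <- function() {
  tree <- ape::read.tree(
    text = "(((A:1,B:2):1,(C:1.5,D:0.5):0.5):2,(E:2,F:1):2);")
  traits <- withr::with_seed(1234,
    matrix(rnorm(6 * 10), 6, 10,
           dimnames = list(LETTERS[1:6], sprintf("trait%02d", 1:10))))
  communities <- rbind(
    lake1 = c(A = 1, B = 1, C = 0, D = 0, E = 0, F = 0),
    lake2 = c(A = 1, B = 0, C = 1, D = 1, E = 0, F = 0),
    lake3 = c(A = 0, B = 0, C = 0, D = 0, E = 1, F = 1))
  lakes <- data.frame(lake_id = paste0("lake", 1:3),
                      area = c(10, 100, 50), elevation = c(5, 300, 150),
                      latitude = c(56, 62, 67), longitude = c(13, 15, 19))
  records <- data.frame(
    lake_id = c("lake1", "lake1", "lake2", "lake3", "lake3"),
    species_id = c("E", "F", "E", "A", "B"),
    outcome = c(1L, 0L, 1L, 0L, 1L))
  list(tree = tree, traits = traits, communities = communities,
       lakes = lakes, records = records,
       Dphy = cophenetic_distances(tree),
       Dfun = functional_distances(
         trait_pca(traits, npc = 5)))
}
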