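# Main configuration: every parameter the benchmark understands, with
# its default. User configs override individual keys only.

[data]
expression =
metadata =
sample_id_column = sample_id
label_attribute = condition
expression_b =
metadata_b =
mapping =
orientation = auto

[preprocessing]
max_missing_feature = 0.5
max_missing_sample = 0.5

[knowledge]
associations =
gmt =
edges =
terms =
min_score = 0

[selection]
selectors = anova
lambda = 0.05
k_stat = 10
k_kb = 10
n_pathways = 5
n_permutations = 200
missing_policy = epsilon
epsilon = 0.001
aggregation = max

[evaluation]
classifiers = naive_bayes,logistic_regression,svm,random_forest,knn3
cv_k = 10
sizes = 1:20
seed = 1
enrichment_gmt =
cross_dataset = true
top_n = 20

[output]
dir =
verbose = false
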