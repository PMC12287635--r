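# Hypothesized data-generating process for daily active minutes of a pet dog.
# Editable input: one edge per line "parent -> child"; "name [latent]" marks
# a node as unobserved. Node names match the analysis-table column names.
exercise_opportunity [latent]
dog_age -> active_minutes
dog_age -> weight_status
dog_age -> unhealthy_diagnosis
dog_age -> injury
breed_size -> active_minutes
breed_size -> weight_status
breed_size -> unhealthy_diagnosis
sex -> active_minutes
sex -> neuter_status
neuter_status -> active_minutes
neuter_status -> weight_status
weight_status -> active_minutes
weight_status -> unhealthy_diagnosis
unhealthy_diagnosis -> active_minutes
injury -> active_minutes
owner_age -> active_minutes
owner_age -> breed_size
location_type -> breed_size
location_type -> exercise_opportunity
location_type -> active_minutes
climate -> exercise_opportunity
climate -> active_minutes
exercise_opportunity -> active_minutes
latitude -> climate
latitude -> active_minutes
season -> active_minutes
day_type -> active_minutes
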