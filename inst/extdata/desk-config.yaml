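# Desk-scale configuration: reduced model and training budget for CPU runs.
# Keys mirror model_config()/train_config(); swin_* keys map to swin_config().
input_size: 112
mpcm_patches: [2, 4, 8]
filters: 32
depth: 2
mpst_grids: [14, 7]
token_dim: 64
swin_window: 7
swin_heads: 4
swin_mlp_dim: 64
swin_dropout_rate: 0.1
swin_cycles_per_branch: 2
learning_rate: 0.001
batch_size: 16
epochs: 30
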