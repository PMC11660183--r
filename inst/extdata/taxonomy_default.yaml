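# Default conversion from source-directory tags/flags to the ten food
# retail classes. Records whose meta-category is outside the allowlist
# receive no labels. Restaurant-subcategory tags yield FastFood and/or
# Restaurant only via the surveyor 'quick-bites' / 'dine-in' flags.
# Tag lists for classes whose source vocabulary is not publicly
# documented (Specialty, Discount, JuiceCoffee, SweetsDesserts,
# AlcoholStore, AlcoholBar) are plausible, non-canonical defaults meant
# for synthetic data; extend them for a real directory.
meta_allowlist: [Food, Essentials, Drink]
rules:
  - rule_id: grocery_core
    any_of_tags: [supermarket, grocery store]
    disqualify_if_only: [convenience store]
    emit: [Grocery]
  - rule_id: convenience_core
    any_of_tags: [convenience store, bodega, mini market, candy & lotto]
    emit: [Convenience]
  - rule_id: restaurant_subcategory_quick_bites
    any_of_tags: [kosher delicatessen, bagel shop, pizzeria, taqueria,
                  french cafe, diner, deli, sandwich shop, burger joint,
                  gyro shop, fried chicken restaurant]
    required_flags: [quick-bites]
    emit: [FastFood]
  - rule_id: restaurant_subcategory_dine_in
    any_of_tags: [kosher delicatessen, bagel shop, pizzeria, taqueria,
                  french cafe, diner, deli, sandwich shop, burger joint,
                  gyro shop, fried chicken restaurant]
    required_flags: [dine-in]
    emit: [Restaurant]
  - rule_id: fast_food_direct
    any_of_tags: [fast food, chain fast food]
    emit: [FastFood]
  - rule_id: restaurant_direct
    any_of_tags: [restaurant, sit-down restaurant]
    emit: [Restaurant]
  - rule_id: specialty_foods
    any_of_tags: [cheese shop, butcher, fish market, fruit stand,
                  health food store, international market, meat market]
    emit: [SpecialtyFoods]
  - rule_id: discount_store
    any_of_tags: [99 cents store, dollar store, discount store]
    emit: [Discount]
  - rule_id: alcohol_store
    any_of_tags: [liquor store, wine store, wine & spirits]
    emit: [AlcoholStore]
  - rule_id: alcohol_bar
    any_of_tags: [bar, pub, tavern, cocktail bar, wine bar]
    emit: [AlcoholBar]
  - rule_id: juice_coffee
    any_of_tags: [coffee shop, cafe, juice bar, smoothie shop, tea shop,
                  bubble tea]
    emit: [JuiceCoffee]
  - rule_id: sweets_desserts
    any_of_tags: [bakery, dessert shop, ice cream shop, candy store,
                  donut shop]
    emit: [SweetsDesserts]
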